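## Forward simulator of a backcross-derived NAM population.
##
## Design: one fully inbred elite recurrent parent crossed to n_families
## fully inbred wild donors; F1 backcrossed once to the elite parent, then
## three selfing generations by single-seed descent yield the genotyped
## early-generation (BC1S3) plants. Each line is then propagated through
## multi-season field plots (selfed bulk with ear harvesting) with optional
## per-locus viability/harvest selection, and the final cohort is genotyped
## through a pooled DNA sample with a tolerance-based allele caller.
##
## Alleles are coded 0 (elite) / 1 (wild) on haplotypes. Recombination uses
## a no-interference model: per chromosome the crossover count is Poisson
## with mean span/100 cM and positions are uniform on the span (Haldane).

## Crossover mask for one gamete: TRUE = take haplotype 1 at that position.
.cross_mask <- function(pos, len) {
  k <- if (len > 0) stats::rpois(1L, len / 100) else 0L
  st <- stats::runif(1L) < 0.5
  if (k == 0L) return(rep(st, length(pos)))
  bp <- sort(stats::runif(k, 0, len))
  xor(st, (findInterval(pos, bp) %% 2L) == 1L)
}

## One gamete from a 2 x m haplotype matrix at positions pos (span len).
.gam <- function(hap, pos, len) {
  mask <- .cross_mask(pos, len)
  out <- hap[2L, ]
  out[mask] <- hap[1L, mask]
  out
}

## Gametes for a block of seeds: mothers M1/M2 (k x m haplotype matrices),
## midx the mother row per seed. Zero-crossover gametes (the common case)
## are copied in bulk; gametes with crossovers are built individually.
.gam_block <- function(M1, M2, midx, pos, len) {
  n <- length(midx)
  m <- length(pos)
  G <- matrix(0L, n, m)
  k <- if (len > 0) stats::rpois(n, len / 100) else integer(n)
  st <- stats::runif(n) < 0.5
  z1 <- which(k == 0L & st)
  z2 <- which(k == 0L & !st)
  if (length(z1)) G[z1, ] <- M1[midx[z1], , drop = FALSE]
  if (length(z2)) G[z2, ] <- M2[midx[z2], , drop = FALSE]
  for (j in which(k > 0L)) {
    bp <- sort(stats::runif(k[j], 0, len))
    mask <- xor(st[j], (findInterval(pos, bp) %% 2L) == 1L)
    a <- M2[midx[j], ]
    a[mask] <- M1[midx[j], mask]
    G[j, ] <- a
  }
  G
}

#' Simulate NAM founder genomes
#'
#' One homozygous-elite recurrent parent plus \code{n_families} fully inbred
#' wild donors. Each donor carries the wild allele at an independent random
#' subset of SNPs (fraction \code{wild_polymorphism_rate}) and the elite
#' allele elsewhere; only these family-polymorphic SNPs can segregate within
#' the corresponding family.
#'
#' @param n_families number of donor families.
#' @param map genetic map (see [check_map()]).
#' @param wild_polymorphism_rate per-SNP probability that a donor carries the
#'   wild allele; must be in (0, 1].
#' @param seed optional integer seed.
#' @return object of class \code{"heb_founders"}: list with \code{family}
#'   (labels) and \code{mask} (families x SNPs logical matrix of
#'   donor-polymorphic SNPs).
#' @export
sim_founders <- function(n_families = 25, map, wild_polymorphism_rate = 1,
                         seed = NULL) {
  map <- check_map(map)
  if (n_families < 1) stop("'n_families' must be >= 1")
  if (!is.numeric(wild_polymorphism_rate) || length(wild_polymorphism_rate) != 1L ||
      wild_polymorphism_rate <= 0 || wild_polymorphism_rate > 1)
    stop("'wild_polymorphism_rate' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  fam <- sprintf("F%02d", seq_len(n_families))
  mask <- matrix(stats::runif(n_families * nrow(map)) <= wild_polymorphism_rate,
                 n_families, nrow(map),
                 dimnames = list(fam, map$snp))
  if (wild_polymorphism_rate == 1) mask[] <- TRUE
  structure(list(family = fam, mask = mask, map = map),
            class = "heb_founders")
}

#' Draw one gamete from a plant genome
#'
#' Recombination per chromosome: crossover count Poisson with mean equal to
#' the chromosome's cM span / 100, positions uniform, no interference
#' (Haldane model). The gamete is a mosaic of the two parental haplotypes.
#'
#' @param plant list with components \code{hap1} and \code{hap2}: integer
#'   allele vectors (0 = elite, 1 = wild) aligned to the map rows.
#' @param map genetic map.
#' @param seed optional integer seed.
#' @return integer haplotype vector aligned to the map.
#' @export
sim_gamete <- function(plant, map, seed = NULL) {
  map <- check_map(map)
  if (length(plant$hap1) != nrow(map) || length(plant$hap2) != nrow(map))
    stop("plant haplotypes must align with the map")
  if (!is.null(seed)) set.seed(seed)
  out <- integer(nrow(map))
  for (sg in .map_segments(map)) {
    hap <- rbind(plant$hap1[sg$idx], plant$hap2[sg$idx])
    out[sg$idx] <- .gam(hap, sg$pos, sg$len)
  }
  out
}

#' Simulate the genotyped early-generation (BC1S3) population
#'
#' For each family: F1 = donor x elite, BC1 = F1 x elite, then three selfing
#' generations by single-seed descent. The resulting single plants are
#' genotyped with perfect calling. Under this design each plant is expected
#' to be 71.875% homozygous elite, 6.25% heterozygous and 21.875% homozygous
#' wild at family-polymorphic SNPs.
#'
#' @param founders result of [sim_founders()].
#' @param lines_per_family number of independent lines per family.
#' @param seed optional integer seed.
#' @return object of class \code{"heb_pop"}: list with \code{g0} (genotype
#'   matrix, see [genotypes()]), \code{map}, and \code{lines} (internal
#'   reduced haplotype representation used by the propagation step).
#' @export
sim_bc1s3 <- function(founders, lines_per_family = 20, seed = NULL) {
  if (!inherits(founders, "heb_founders")) stop("'founders' must come from sim_founders()")
  if (lines_per_family < 1) stop("'lines_per_family' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  segs <- .map_segments(map)
  n_snp <- nrow(map)
  n_lines <- length(founders$family) * lines_per_family
  g0 <- matrix(0L, n_lines, n_snp,
               dimnames = list(character(n_lines), map$snp))
  lines <- vector("list", n_lines)
  fam_of <- character(n_lines)
  r <- 0L
  for (f in seq_along(founders$family)) {
    poly <- founders$mask[f, ]
    ## per-chromosome view of the family-polymorphic loci
    fsegs <- lapply(segs, function(sg) {
      keep <- poly[sg$idx]
      if (!any(keep)) return(NULL)
      pos <- sg$pos[keep]
      list(idx = sg$idx[keep], pos = pos - min(pos),
           len = max(pos) - min(pos))
    })
    fsegs <- Filter(Negate(is.null), fsegs)
    for (l in seq_len(lines_per_family)) {
      r <- r + 1L
      id <- sprintf("%s_%03d", founders$family[f], l)
      rownames(g0)[r] <- id
      fam_of[r] <- founders$family[f]
      chrom <- lapply(fsegs, function(sg) {
        m <- length(sg$idx)
        ## F1 is heterozygous at every family-polymorphic locus;
        ## BC1 receives one F1 gamete plus an elite gamete.
        f1 <- rbind(rep(0L, m), rep(1L, m))
        hap <- rbind(.gam(f1, sg$pos, sg$len), rep(0L, m))
        for (i in 1:3) # three selfings, single-seed descent
          hap <- rbind(.gam(hap, sg$pos, sg$len), .gam(hap, sg$pos, sg$len))
        list(idx = sg$idx, pos = sg$pos, len = sg$len, hap = hap)
      })
      for (cc in chrom) g0[r, cc$idx] <- cc$hap[1L, ] + cc$hap[2L, ]
      lines[[r]] <- list(id = id, family = founders$family[f], chrom = chrom)
    }
  }
  structure(list(g0 = genotypes(g0, fam_of), map = map, lines = lines),
            class = "heb_pop")
}

#' Field-propagation schedule
#'
#' One row per season: the number of plants sown (selfed seeds pooled from
#' the previous season's harvested mother plants) and the number of ears
#' (mother plants) harvested. The final season is the cohort sampled for
#' pooled genotyping and is not harvested. The default follows the
#' propagation design of the emulated experiment: plot of 60 plants grown
#' from the genotyped plant's seed, then 60, 60 and 100 plants sown in
#' consecutive seasons with 20 ears harvested each year, and finally 20
#' plants grown for pooled sampling — five selfing generations in total.
#'
#' @param n_sown integer vector, plants sown per season.
#' @param n_ears integer vector, ears harvested per season (last entry
#'   ignored; use 0).
#' @return data frame with columns \code{n_sown}, \code{n_ears}.
#' @export
heb_schedule <- function(n_sown = c(60, 60, 60, 100, 20),
                         n_ears = c(20, 20, 20, 20, 0)) {
  if (length(n_sown) == 0L) stop("schedule must have at least one season")
  if (length(n_ears) != length(n_sown))
    stop("'n_sown' and 'n_ears' must have the same length")
  if (any(n_sown < 1)) stop("'n_sown' must be >= 1 in every season")
  ns <- length(n_sown)
  if (ns > 1L && any(n_ears[-ns] < 1))
    stop("'n_ears' must be >= 1 in every harvested season")
  if (any(n_ears[-ns] > n_sown[-ns]))
    stop("cannot harvest more ears than plants sown")
  data.frame(n_sown = as.integer(n_sown), n_ears = as.integer(n_ears))
}

#' Per-locus selection model
#'
#' Fitness of the genotype classes at a selected locus is 1 (elite
#' homozygote), 1 + h*s (heterozygote) and 1 + s (wild homozygote),
#' multiplicative across loci. Positive s favours the wild allele. The
#' \code{phase} distinguishes selection acting through plant survival and
#' competition in the plot ("viability") from selection through the choice
#' of harvested ears ("harvest"); both bias which plants mother the next
#' season.
#'
#' @param snp SNP identifiers of the selected loci.
#' @param s selection coefficients (> -1).
#' @param h dominance coefficients in [0, 1].
#' @param phase "viability" or "harvest".
#' @return data frame of class \code{"selection_model"}.
#' @export
selection_model <- function(snp, s, h = 0.5, phase = "viability") {
  out <- data.frame(snp = as.character(snp), s = s, h = h, phase = phase)
  if (any(out$s <= -1)) stop("'s' must be > -1 (fitness must stay positive)")
  if (any(out$h < 0 | out$h > 1)) stop("'h' must be in [0, 1]")
  if (!all(out$phase %in% c("viability", "harvest")))
    stop("'phase' must be \"viability\" or \"harvest\"")
  if (anyDuplicated(out$snp)) stop("duplicated selected SNPs")
  class(out) <- c("selection_model", "data.frame")
  out
}

## Multiplicative fitness for a dosage matrix D (plants x selected loci).
.fitness <- function(D, s, h) {
  if (ncol(D) == 0L) return(rep(1, nrow(D)))
  W <- 1 + sweep(D == 1L, 2L, h * s, `*`) + sweep(D == 2L, 2L, s, `*`)
  apply(W, 1L, prod)
}

## Core propagation over a line's segregating loci only. hap1/hap2: allele
## vectors over the tracked loci; segs: per-chromosome list(cols, pos, len)
## indexing into the tracked vector; sel: list(cols, s, h, phase) over
## tracked loci. Returns the final sown cohort as haplotype matrices.
.propagate_core <- function(hap1, hap2, segs, schedule, sel = NULL) {
  m <- length(hap1)
  M1 <- matrix(as.integer(hap1), 1L)
  M2 <- matrix(as.integer(hap2), 1L)
  ns <- nrow(schedule)
  for (i in seq_len(ns)) {
    n <- schedule$n_sown[i]
    midx <- if (nrow(M1) == 1L) rep(1L, n) else
      sample.int(nrow(M1), n, replace = TRUE)
    A1 <- matrix(0L, n, m)
    A2 <- matrix(0L, n, m)
    for (sg in segs) {
      cl <- sg$cols
      A1[, cl] <- .gam_block(M1[, cl, drop = FALSE], M2[, cl, drop = FALSE],
                             midx, sg$pos, sg$len)
      A2[, cl] <- .gam_block(M1[, cl, drop = FALSE], M2[, cl, drop = FALSE],
                             midx, sg$pos, sg$len)
    }
    if (i == ns) return(list(A1 = A1, A2 = A2))
    w <- rep(1, n)
    if (!is.null(sel) && length(sel$cols)) {
      D <- A1[, sel$cols, drop = FALSE] + A2[, sel$cols, drop = FALSE]
      w <- .fitness(D, sel$s, sel$h)
    }
    keep <- sample.int(n, schedule$n_ears[i], replace = FALSE, prob = w)
    M1 <- A1[keep, , drop = FALSE]
    M2 <- A2[keep, , drop = FALSE]
  }
}

## Build the tracked-locus view (segs + selection) for a set of global SNP
## column indices 'cols' (sorted) of the map.
.tracked_segs <- function(map_segs, cols) {
  segs <- list()
  for (sg in map_segs) {
    keep <- which(sg$idx %in% cols)
    if (!length(keep)) next
    pos <- sg$pos[keep]
    segs[[length(segs) + 1L]] <-
      list(cols = match(sg$idx[keep], cols), pos = pos - min(pos),
           len = max(pos) - min(pos))
  }
  segs
}

.tracked_selection <- function(selection, map, cols) {
  if (is.null(selection) || nrow(selection) == 0L) return(NULL)
  gidx <- match(selection$snp, map$snp)
  if (anyNA(gidx)) stop("selected SNPs absent from the map: ",
                        paste(selection$snp[is.na(gidx)], collapse = ", "))
  hit <- which(gidx %in% cols)
  if (!length(hit)) return(NULL)
  list(cols = match(gidx[hit], cols), s = selection$s[hit],
       h = selection$h[hit], phase = selection$phase[hit])
}

#' Propagate one line through the field-plot schedule
#'
#' Season loop: sow \code{n_sown} selfed seeds pooled from the previous
#' season's harvested mother plants (first season: selfed seeds of the input
#' plant); compute per-plant fitness from the selection model; harvest
#' \code{n_ears} mother plants without replacement with probability
#' proportional to fitness. The final season's sown cohort is returned.
#'
#' @param plant list with \code{hap1}, \code{hap2} allele vectors aligned to
#'   the map (0 = elite, 1 = wild).
#' @param map genetic map.
#' @param schedule propagation schedule (see [heb_schedule()]).
#' @param selection optional [selection_model()].
#' @param seed optional integer seed.
#' @return list of plant genomes (each \code{list(hap1, hap2)}).
#' @export
propagate_line <- function(plant, map, schedule, selection = NULL,
                           seed = NULL) {
  map <- check_map(map)
  if (length(plant$hap1) != nrow(map) || length(plant$hap2) != nrow(map))
    stop("plant haplotypes must align with the map")
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    stop("'schedule' must be a non-empty schedule (see heb_schedule())")
  if (!is.null(seed)) set.seed(seed)
  het <- which(plant$hap1 != plant$hap2)
  segs <- .tracked_segs(.map_segments(map), het)
  sel <- .tracked_selection(selection, map, het)
  fin <- .propagate_core(plant$hap1[het], plant$hap2[het], segs, schedule, sel)
  n <- nrow(fin$A1)
  lapply(seq_len(n), function(r) {
    h1 <- plant$hap1; h1[het] <- fin$A1[r, ]
    h2 <- plant$hap2; h2[het] <- fin$A2[r, ]
    list(hap1 = h1, hap2 = h2)
  })
}

## Tolerance-based pooled caller on wild-allele copy counts. 'wild' is the
## count of wild allele copies per SNP over 2 * pool_n copies.
.pooled_call <- function(wild, total, minor_tolerance) {
  minor <- pmin(wild, total - wild) / total
  out <- rep(1L, length(wild))
  hom <- minor <= minor_tolerance
  out[hom & wild > total - wild] <- 2L
  out[hom & wild < total - wild] <- 0L
  out
}

#' Pooled DNA sampling and tolerance-based allele calling
#'
#' Samples \code{pool_size} plants uniformly without replacement from a
#' cohort and calls each SNP from the pooled allele counts: homozygous for
#' the majority allele when the minor-allele fraction is at most
#' \code{minor_tolerance} (mimicking the calling tolerance of array-based
#' genotyping of pooled DNA), heterozygous otherwise. Calls fail to missing
#' independently with probability \code{failure_rate}.
#'
#' @param cohort list of plant genomes (\code{list(hap1, hap2)}).
#' @param pool_size number of plants pooled.
#' @param minor_tolerance maximum minor-allele fraction still called
#'   homozygous; in [0, 0.5).
#' @param failure_rate per-SNP probability of a missing call.
#' @param seed optional integer seed.
#' @return integer genotype vector (0/1/2/NA) across SNPs.
#' @export
pool_and_call <- function(cohort, pool_size = 12, minor_tolerance = 0.2,
                          failure_rate = 0, seed = NULL) {
  if (pool_size < 1 || pool_size > length(cohort))
    stop("'pool_size' must be between 1 and the cohort size")
  if (minor_tolerance < 0 || minor_tolerance >= 0.5)
    stop("'minor_tolerance' must be in [0, 0.5)")
  if (failure_rate < 0 || failure_rate > 1)
    stop("'failure_rate' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pick <- sample.int(length(cohort), pool_size)
  wild <- Reduce(`+`, lapply(cohort[pick],
                             function(p) p$hap1 + p$hap2))
  calls <- .pooled_call(wild, 2L * pool_size, minor_tolerance)
  if (failure_rate > 0)
    calls[stats::runif(length(calls)) < failure_rate] <- NA_integer_
  calls
}

#' Simulate a full temporal-genotyping experiment
#'
#' End-to-end wrapper: founders, BC1S3 population with perfect single-plant
#' calls (\code{g0}), per-line field propagation under the schedule and
#' selection model, pooled sampling of the final cohort and tolerance-based
#' calling (\code{g8}). The two matrices share line and SNP sets, and the
#' selection model is returned as the ground truth for recovery tests.
#'
#' @param map genetic map (e.g. [sim_genetic_map()]).
#' @param n_families number of donor families.
#' @param lines_per_family lines per family.
#' @param schedule propagation schedule (see [heb_schedule()]).
#' @param selection optional [selection_model()]; \code{NULL} = neutral.
#' @param wild_polymorphism_rate per-SNP donor polymorphism probability.
#' @param pool_size plants pooled per line in the final season.
#' @param minor_tolerance pooled-call tolerance (see [pool_and_call()]).
#' @param failure_rate per-call missing probability in \code{g8}.
#' @param seed integer seed; fully determines the simulation.
#' @return object of class \code{"heb_sim"}: list with \code{g0}, \code{g8}
#'   (genotype matrices), \code{map}, \code{truth} (the selection model) and
#'   \code{config}.
#' @export
sim_heb_experiment <- function(map, n_families = 25, lines_per_family = 20,
                               schedule = heb_schedule(), selection = NULL,
                               wild_polymorphism_rate = 1, pool_size = 12,
                               minor_tolerance = 0.2, failure_rate = 0,
                               seed = NULL) {
  map <- check_map(map)
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    stop("'schedule' must be a non-empty schedule (see heb_schedule())")
  ns <- nrow(schedule)
  if (pool_size > schedule$n_sown[ns])
    stop("'pool_size' exceeds the final-season cohort size")
  if (!is.null(selection) && !inherits(selection, "selection_model"))
    stop("'selection' must come from selection_model()")
  if (!is.null(seed)) set.seed(seed)
  founders <- sim_founders(n_families, map, wild_polymorphism_rate)
  pop <- sim_bc1s3(founders, lines_per_family)
  g0 <- pop$g0
  map_segs <- .map_segments(map)
  g8 <- g0
  attr(g8, "family") <- attr(g0, "family")
  n_snp <- nrow(map)
  for (r in seq_along(pop$lines)) {
    line <- pop$lines[[r]]
    ## loci still heterozygous in the genotyped BC1S3 plant are the only
    ## ones that can change during selfed propagation
    het_global <- unlist(lapply(line$chrom, function(cc)
      cc$idx[cc$hap[1L, ] != cc$hap[2L, ]]), use.names = FALSE)
    row8 <- g0[r, ]
    if (length(het_global)) {
      het_global <- sort(het_global)
      h1 <- integer(length(het_global))
      h2 <- integer(length(het_global))
      for (cc in line$chrom) {
        hit <- which(cc$idx %in% het_global)
        at <- match(cc$idx[hit], het_global)
        h1[at] <- cc$hap[1L, hit]
        h2[at] <- cc$hap[2L, hit]
      }
      segs <- .tracked_segs(map_segs, het_global)
      sel <- .tracked_selection(selection, map, het_global)
      fin <- .propagate_core(h1, h2, segs, schedule, sel)
      pick <- sample.int(nrow(fin$A1), pool_size)
      wild <- colSums(fin$A1[pick, , drop = FALSE]) +
        colSums(fin$A2[pick, , drop = FALSE])
      row8[het_global] <- .pooled_call(wild, 2L * pool_size, minor_tolerance)
    }
    if (failure_rate > 0)
      row8[stats::runif(n_snp) < failure_rate] <- NA_integer_
    g8[r, ] <- row8
  }
  structure(list(g0 = g0, g8 = g8, map = map, truth = selection,
                 config = list(n_families = n_families,
                               lines_per_family = lines_per_family,
                               schedule = schedule,
                               wild_polymorphism_rate = wild_polymorphism_rate,
                               pool_size = pool_size,
                               minor_tolerance = minor_tolerance,
                               failure_rate = failure_rate, seed = seed)),
            class = "heb_sim")
}

#' @export
print.heb_sim <- function(x, ...) {
  cat("Simulated NAM temporal-genotyping experiment\n")
  cat(sprintf("  lines: %d (%d families x %d), SNPs: %d\n",
              nrow(x$g0), x$config$n_families, x$config$lines_per_family,
              ncol(x$g0)))
  cat(sprintf("  seasons: %d, pool size: %d, calling tolerance: %.2f\n",
              nrow(x$config$schedule), x$config$pool_size,
              x$config$minor_tolerance))
  nsel <- if (is.null(x$truth)) 0L else nrow(x$truth)
  cat(sprintf("  selected loci: %d\n", nsel))
  invisible(x)
}
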