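#' SNP-level quality filters
#'
#' Applies the marker quality rules to a genotype matrix: a SNP is retained
#' iff it (a) is polymorphic (at least two distinct non-missing genotype
#' classes) within at least one family, (b) has a missing-call fraction
#' strictly below \code{max_failure}, and (c) has a heterozygous-call
#' fraction strictly below \code{max_het}. The heterozygous fraction is
#' computed over non-missing calls; the failure fraction over all lines.
#' All rules are evaluated on the input matrix, so their outcomes do not
#' depend on application order.
#'
#' @param g genotype matrix (see [genotypes()]).
#' @param max_failure maximum tolerated missing-call fraction (default 0.10).
#' @param max_het maximum tolerated heterozygous fraction (default 0.125,
#'   twice the expected early-generation heterozygosity).
#' @param family optional per-line family assignment (defaults to
#'   \code{attr(g, "family")}).
#' @return list with \code{retained} (SNP identifiers passing all rules) and
#'   \code{report} (per-SNP logical columns \code{polymorphic},
#'   \code{failure_ok}, \code{het_ok}, \code{retained} plus the measured
#'   fractions).
#' @export
filter_snps <- function(g, max_failure = 0.10, max_het = 0.125,
                        family = NULL) {
  if (!is.matrix(g) || nrow(g) == 0L || ncol(g) == 0L)
    stop("'g' must be a non-empty genotype matrix")
  fam <- .family_of(g, family)
  n <- nrow(g)
  miss_frac <- colMeans(is.na(g))
  nonmiss <- n - colSums(is.na(g))
  het_frac <- ifelse(nonmiss > 0, colSums(g == 1L, na.rm = TRUE) / nonmiss, 0)
  poly <- rep(FALSE, ncol(g))
  for (f in unique(fam)) {
    sub <- g[fam == f, , drop = FALSE]
    nclass <- apply(sub, 2L, function(col) length(unique(col[!is.na(col)])))
    poly <- poly | nclass >= 2L
  }
  ok_fail <- miss_frac < max_failure
  ok_het <- het_frac < max_het
  keep <- poly & ok_fail & ok_het
  list(retained = colnames(g)[keep],
       report = data.frame(snp = colnames(g), polymorphic = poly,
                           failure_rate = miss_frac, failure_ok = ok_fail,
                           het_rate = het_frac, het_ok = ok_het,
                           retained = keep, row.names = NULL))
}

#' Remove duplicated SNP columns
#'
#' SNPs whose call vectors (including the missingness pattern) are identical
#' across all lines are in complete linkage disequilibrium in the data; only
#' the first of each group in map order is kept.
#'
#' @param g genotype matrix with columns in map order.
#' @return list with \code{retained} (kept SNP identifiers) and
#'   \code{duplicates} (data frame mapping each dropped SNP to the kept
#'   representative, with the group size).
#' @export
drop_duplicate_snps <- function(g) {
  key <- apply(g, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  kept_of <- colnames(g)[first][match(key, key[first])]
  size <- as.vector(table(key)[key])
  dup <- data.frame(dropped = colnames(g)[!first],
                    kept = kept_of[!first],
                    group_size = size[!first], row.names = NULL)
  list(retained = colnames(g)[first], duplicates = dup)
}

#' Drop lines with inconsistent genotypes between generations
#'
#' A line's mismatch rate is the fraction of SNPs called homozygous in the
#' early generation whose later-generation call is the opposite homozygote —
#' changes that selfing alone cannot produce. Lines with a rate strictly
#' above \code{max_mismatch} are flagged as mislabelled or contaminated and
#' dropped.
#'
#' @param g0,g8 genotype matrices sharing line and SNP identifiers.
#' @param max_mismatch maximum tolerated opposite-homozygote rate.
#' @return list with \code{retained} (line identifiers), \code{mismatch}
#'   (named per-line rate) and \code{dropped}.
#' @export
filter_lines <- function(g0, g8, max_mismatch = 0.05) {
  al <- align_genotypes(g0, g8)
  hom0 <- al$g0 == 0L | al$g0 == 2L
  hom0[is.na(hom0)] <- FALSE
  flip <- hom0 & !is.na(al$g8) & (al$g8 == 2L - al$g0)
  n_hom <- rowSums(hom0)
  rate <- ifelse(n_hom > 0, rowSums(flip) / n_hom, 0)
  names(rate) <- rownames(al$g0)
  keep <- rate <= max_mismatch
  list(retained = names(rate)[keep], mismatch = rate,
       dropped = names(rate)[!keep])
}

#' Minimum heterozygous-line filter for fixation statistics
#'
#' AFR and RFD are only meaningful for SNPs with enough initially
#' heterozygous lines; SNPs with fewer than \code{min_het_lines}
#' heterozygous calls in the early-generation matrix are excluded to avoid
#' strong small-denominator bias.
#'
#' @param g0 early-generation genotype matrix.
#' @param min_het_lines minimum count of heterozygous calls (default 10).
#' @return character vector of retained SNP identifiers.
#' @export
min_het_snps <- function(g0, min_het_lines = 10) {
  colnames(g0)[colSums(g0 == 1L, na.rm = TRUE) >= min_het_lines]
}

#' Full QC pipeline for paired genotype matrices
#'
#' Applies [filter_snps()] to each matrix, intersects the retained SNP sets,
#' removes duplicated columns (on the early-generation matrix, in map
#' order), and drops inconsistent lines. The minimum-heterozygosity filter
#' is left to the scan stage, which needs the unfiltered denominators.
#'
#' @inheritParams filter_lines
#' @param map genetic map used to order SNP columns.
#' @param max_failure,max_het SNP-rule thresholds (see [filter_snps()]).
#' @param max_mismatch line-rule threshold (see [filter_lines()]).
#' @return list with filtered \code{g0}, \code{g8} and a \code{report} list
#'   holding each stage's output.
#' @export
qc_pipeline <- function(g0, g8, map, max_failure = 0.10, max_het = 0.125,
                        max_mismatch = 0.05) {
  map <- check_map(map)
  al <- align_genotypes(g0, g8)
  snps <- map$snp[map$snp %in% colnames(al$g0)]
  fam <- .family_of(al$g0)
  g0m <- genotypes(al$g0[, snps, drop = FALSE], fam)
  g8m <- genotypes(al$g8[, snps, drop = FALSE], fam)
  f0 <- filter_snps(g0m, max_failure, max_het)
  f8 <- filter_snps(g8m, max_failure, max_het)
  keep <- intersect(f0$retained, f8$retained)
  keep <- snps[snps %in% keep]
  dup <- drop_duplicate_snps(g0m[, keep, drop = FALSE])
  keep <- dup$retained
  g0m <- genotypes(g0m[, keep, drop = FALSE], fam)
  g8m <- genotypes(g8m[, keep, drop = FALSE], fam)
  fl <- filter_lines(g0m, g8m, max_mismatch)
  fam2 <- fam[match(fl$retained, rownames(g0m))]
  list(g0 = genotypes(g0m[fl$retained, , drop = FALSE], fam2),
       g8 = genotypes(g8m[fl$retained, , drop = FALSE], fam2),
       report = list(snps_g0 = f0$report, snps_g8 = f8$report,
                     duplicates = dup$duplicates, lines = fl))
}
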