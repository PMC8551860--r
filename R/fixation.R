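#' Build the reconstructed fixation matrix
#'
#' For every line-by-SNP entry that was heterozygous in the early generation,
#' the later-generation call is recoded as a fixation value: -1 when fixed
#' for the homozygous elite allele, +1 when fixed for the homozygous wild
#' allele, 0 when the (reconstructed) heterozygosity was retained, NA when
#' the later call is missing. Entries not initially heterozygous are masked
#' and never counted.
#'
#' @param g0 early-generation genotype matrix (single-plant calls).
#' @param g8 later-generation genotype matrix (pooled-progeny calls),
#'   sharing line and SNP identifiers with \code{g0}.
#' @return integer lines-by-SNPs matrix of class \code{"fixation_matrix"}
#'   with values -1/0/+1/NA and a logical attribute \code{"het0"} marking
#'   the initially heterozygous (unmasked) entries.
#' @export
build_fixation_matrix <- function(g0, g8) {
  if (!is.matrix(g0) || !is.matrix(g8)) stop("inputs must be matrices")
  if (!identical(dim(g0), dim(g8)) ||
      !identical(rownames(g0), rownames(g8)) ||
      !identical(colnames(g0), colnames(g8)))
    stop("'g0' and 'g8' must share dimensions and line/SNP identifiers; ",
         "align them first (see align_genotypes)")
  het0 <- !is.na(g0) & g0 == 1L
  fm <- matrix(NA_integer_, nrow(g0), ncol(g0), dimnames = dimnames(g0))
  fm[het0] <- g8[het0] - 1L
  structure(fm, het0 = het0, class = "fixation_matrix")
}

#' Per-SNP fixation summary: AFR and RFD
#'
#' For each SNP, counts the initially heterozygous lines (\code{n_het0}),
#' the lines fixed toward the elite (\code{n_elite}, value -1) and wild
#' (\code{n_wild}, value +1) alleles, and the lines retaining heterozygosity
#' (\code{n_ret}), and computes
#' \describe{
#'   \item{AFR}{allele fixation rate, \code{(n_elite + n_wild) / n_het0}.}
#'   \item{RFD}{relative fixation direction,
#'     \code{(n_wild - n_elite) / n_het0}; positive values mean the wild
#'     allele was fixed preferentially.}
#' }
#' By default missing later-generation calls stay in the denominator (it
#' counts early-generation heterozygous calls only); with
#' \code{complete_pairs = TRUE} the denominator is restricted to entries
#' with a non-missing later call.
#'
#' @param fm fixation matrix from [build_fixation_matrix()].
#' @param map optional genetic map; when given, \code{chrom} and \code{cM}
#'   columns are attached and rows are map-ordered.
#' @param complete_pairs use only complete line pairs in the denominator.
#' @return data frame with one row per SNP: \code{snp}, optional
#'   \code{chrom}/\code{cM}, \code{n_het0}, \code{n_elite}, \code{n_wild},
#'   \code{n_ret}, \code{n_miss}, \code{AFR}, \code{RFD}. SNPs with a zero
#'   denominator get NA statistics.
#' @export
fixation_summary <- function(fm, map = NULL, complete_pairs = FALSE) {
  if (!inherits(fm, "fixation_matrix"))
    stop("'fm' must come from build_fixation_matrix()")
  het0 <- attr(fm, "het0")
  n_het0 <- colSums(het0)
  n_elite <- colSums(fm == -1L, na.rm = TRUE)
  n_wild <- colSums(fm == 1L, na.rm = TRUE)
  n_ret <- colSums(fm == 0L, na.rm = TRUE)
  n_miss <- n_het0 - (n_elite + n_wild + n_ret)
  denom <- if (complete_pairs) n_elite + n_wild + n_ret else n_het0
  afr <- ifelse(denom > 0, (n_elite + n_wild) / denom, NA_real_)
  rfd <- ifelse(denom > 0, (n_wild - n_elite) / denom, NA_real_)
  out <- data.frame(snp = colnames(fm), n_het0 = n_het0, n_elite = n_elite,
                    n_wild = n_wild, n_ret = n_ret, n_miss = n_miss,
                    AFR = afr, RFD = rfd, row.names = NULL)
  if (!is.null(map)) {
    map <- check_map(map)
    out <- merge(out, map, by = "snp", sort = FALSE)
    chrom_rank <- match(out$chrom, unique(map$chrom))
    out <- out[order(chrom_rank, out$cM, out$snp), ]
    rownames(out) <- NULL
    out <- out[, c("snp", "chrom", "cM", "n_het0", "n_elite", "n_wild",
                   "n_ret", "n_miss", "AFR", "RFD")]
  }
  out
}

#' Sliding-window chi-square scan of fixation direction
#'
#' Slides a window of \code{window} consecutive SNPs (step \code{step},
#' never spanning chromosome boundaries) along the map-ordered per-SNP
#' summaries, sums the elite- and wild-fixed counts over the member SNPs,
#' and tests the summed counts against the neutral 1:1 expectation with a
#' 1-df chi-square goodness-of-fit statistic,
#' \code{(n_elite - n_wild)^2 / (n_elite + n_wild)}. Windows with no fixed
#' alleles are flagged untestable (the statistic is undefined at 0/0).
#'
#' @param summaries per-SNP summary with \code{chrom} and \code{cM} columns
#'   (see [fixation_summary()] with a map).
#' @param window number of consecutive SNPs per window.
#' @param step window step in SNPs (1 = fully overlapping).
#' @return data frame with one row per window: chromosome, start/end SNP and
#'   cM, member count, summed counts, mean window AFR/RFD, \code{chisq},
#'   \code{p} and \code{testable}.
#' @export
sliding_windows <- function(summaries, window = 10, step = 1) {
  if (window < 1 || window != round(window)) stop("'window' must be >= 1")
  if (step < 1 || step != round(step)) stop("'step' must be >= 1")
  if (!all(c("chrom", "cM") %in% names(summaries)))
    stop("'summaries' must carry chrom and cM columns (pass a map to ",
         "fixation_summary)")
  out <- list()
  for (ch in unique(summaries$chrom)) {
    s <- summaries[summaries$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    if (n < window) next
    starts <- seq.int(1L, n - window + 1L, by = step)
    ce <- cumsum(c(0, s$n_elite))
    cw <- cumsum(c(0, s$n_wild))
    ca <- cumsum(c(0, ifelse(is.na(s$AFR), 0, s$AFR)))
    cr <- cumsum(c(0, ifelse(is.na(s$RFD), 0, s$RFD)))
    ends <- starts + window - 1L
    ne <- ce[ends + 1L] - ce[starts]
    nw <- cw[ends + 1L] - cw[starts]
    tot <- ne + nw
    chisq <- ifelse(tot > 0, (ne - nw)^2 / tot, NA_real_)
    out[[ch]] <- data.frame(
      chrom = ch,
      start_snp = s$snp[starts], end_snp = s$snp[ends],
      start_cM = s$cM[starts], end_cM = s$cM[ends],
      n_snps = window,
      n_elite = ne, n_wild = nw,
      AFR_mean = (ca[ends + 1L] - ca[starts]) / window,
      RFD_mean = (cr[ends + 1L] - cr[starts]) / window,
      chisq = chisq,
      p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
      testable = tot > 0,
      row.names = NULL)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start_snp = character(),
                      end_snp = character(), start_cM = numeric(),
                      end_cM = numeric(), n_snps = integer(),
                      n_elite = numeric(), n_wild = numeric(),
                      AFR_mean = numeric(), RFD_mean = numeric(),
                      chisq = numeric(), p = numeric(),
                      testable = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni decision over window tests
#'
#' Flags windows whose p-value falls below \code{alpha} divided by the
#' number of testable windows. Untestable windows are excluded from the
#' correction denominator and never flagged.
#'
#' @param windows window table from [sliding_windows()].
#' @param alpha family-wise significance level (default 0.01).
#' @return the window table with a \code{significant} column; the number of
#'   testable windows and the corrected threshold are attached as attributes
#'   \code{"n_testable"} and \code{"p_threshold"}.
#' @export
bonferroni_scan <- function(windows, alpha = 0.01) {
  n_testable <- sum(windows$testable)
  thr <- if (n_testable > 0) alpha / n_testable else NA_real_
  windows$significant <- windows$testable & !is.na(windows$p) &
    windows$p < thr
  attr(windows, "n_testable") <- n_testable
  attr(windows, "p_threshold") <- thr
  windows
}

#' Fit a temporal fixation selection scan
#'
#' The main model-fitting entry point. Given paired genotype matrices for
#' the same lines at two generations and a genetic map, it
#' \enumerate{
#'   \item recodes initially heterozygous entries into fixation values
#'     (-1/0/+1) via [build_fixation_matrix()],
#'   \item computes per-SNP allele fixation rates (AFR) and relative
#'     fixation directions (RFD), keeping for the scan only SNPs with at
#'     least \code{min_het} initially heterozygous lines,
#'   \item slides a \code{window}-SNP window along each chromosome, testing
#'     the summed elite/wild fixed counts against the neutral 1:1 ratio with
#'     a 1-df chi-square goodness-of-fit test, and
#'   \item flags windows significant at a Bonferroni-corrected level
#'     \code{alpha}.
#' }
#' Input matrices are expected to have passed QC (see [qc_pipeline()]).
#'
#' @param g0 early-generation genotype matrix (single-plant calls).
#' @param g8 later-generation genotype matrix (pooled-progeny calls).
#' @param map genetic map covering the shared SNPs.
#' @param window SNPs per sliding window (default 10).
#' @param step window step (default 1).
#' @param alpha family-wise significance level (default 0.01).
#' @param min_het minimum initially heterozygous lines per scanned SNP
#'   (default 10).
#' @param complete_pairs restrict AFR/RFD denominators to complete pairs.
#' @return object of class \code{"fixation_scan"} with components
#'   \code{snp} (per-SNP summary with a \code{scanned} flag), \code{windows}
#'   (window tests with Bonferroni decisions), \code{fixation} (the
#'   fixation matrix), and scalars \code{n_lines}, \code{n_snps},
#'   \code{n_scanned}, \code{n_testable}, \code{p_threshold},
#'   \code{pooled_afr} (all fixed calls / all initially heterozygous calls)
#'   and \code{mean_afr} (mean of per-SNP AFRs over scanned SNPs).
#'   Supports \code{print}, \code{summary}, \code{coef} and \code{plot}.
#' @examples
#' map <- sim_genetic_map(60, n_chrom = 2)
#' sim <- sim_heb_experiment(map, n_families = 5, lines_per_family = 30,
#'                           seed = 1)
#' fit <- fixation_scan(sim$g0, sim$g8, map)
#' fit
#' head(coef(fit))
#' @export
fixation_scan <- function(g0, g8, map, window = 10, step = 1, alpha = 0.01,
                          min_het = 10, complete_pairs = FALSE) {
  map <- check_map(map)
  al <- align_genotypes(g0, g8)
  snps <- map$snp[map$snp %in% colnames(al$g0)]
  if (length(snps) == 0L) stop("no shared SNPs between map and matrices")
  g0m <- al$g0[, snps, drop = FALSE]
  g8m <- al$g8[, snps, drop = FALSE]
  fm <- build_fixation_matrix(g0m, g8m)
  snp_sum <- fixation_summary(fm, map = map, complete_pairs = complete_pairs)
  snp_sum$scanned <- snp_sum$n_het0 >= min_het
  scanned <- snp_sum[snp_sum$scanned, , drop = FALSE]
  windows <- bonferroni_scan(sliding_windows(scanned, window, step), alpha)
  n_fixed <- sum(snp_sum$n_elite + snp_sum$n_wild)
  n_het_tot <- sum(snp_sum$n_het0)
  structure(list(call = match.call(),
                 snp = snp_sum, windows = windows, fixation = fm,
                 n_lines = nrow(g0m), n_snps = length(snps),
                 n_scanned = nrow(scanned),
                 n_testable = attr(windows, "n_testable"),
                 p_threshold = attr(windows, "p_threshold"),
                 pooled_afr = if (n_het_tot > 0) n_fixed / n_het_tot else NA_real_,
                 mean_afr = mean(scanned$AFR, na.rm = TRUE),
                 window = window, step = step, alpha = alpha,
                 min_het = min_het),
            class = "fixation_scan")
}

#' @export
print.fixation_scan <- function(x, ...) {
  cat("Temporal fixation selection scan\n")
  cat(sprintf("  %d lines, %d SNPs (%d with >= %d initially heterozygous lines)\n",
              x$n_lines, x$n_snps, x$n_scanned, x$min_het))
  cat(sprintf("  pooled fixation fraction: %.3f   mean per-SNP AFR: %.3f\n",
              x$pooled_afr, x$mean_afr))
  cat(sprintf("  windows: %d (%d testable), Bonferroni alpha = %g -> p < %.3g\n",
              nrow(x$windows), x$n_testable, x$alpha, x$p_threshold))
  cat(sprintf("  significant windows: %d\n", sum(x$windows$significant)))
  invisible(x)
}

#' @export
coef.fixation_scan <- function(object, scanned_only = TRUE, ...) {
  s <- object$snp
  if (scanned_only) s <- s[s$scanned, , drop = FALSE]
  out <- s[, c("snp", "chrom", "cM", "n_het0", "AFR", "RFD")]
  rownames(out) <- NULL
  out
}

#' @export
summary.fixation_scan <- function(object, ...) {
  w <- object$windows
  sig <- w[w$significant, , drop = FALSE]
  by_chr <- if (nrow(w) > 0)
    stats::aggregate(significant ~ chrom, data = w, FUN = sum)
  else data.frame(chrom = character(), significant = integer())
  structure(list(scan = object, significant = sig, by_chrom = by_chr,
                 mean_rfd = mean(object$snp$RFD[object$snp$scanned],
                                 na.rm = TRUE)),
            class = "summary.fixation_scan")
}

#' @export
print.summary.fixation_scan <- function(x, ...) {
  print(x$scan)
  cat(sprintf("  mean per-SNP RFD (scanned SNPs): %.4f\n", x$mean_rfd))
  if (nrow(x$significant) > 0) {
    cat("\nSignificant windows (strongest first):\n")
    s <- x$significant[order(x$significant$p), , drop = FALSE]
    print(utils::head(s[, c("chrom", "start_cM", "end_cM", "n_elite",
                            "n_wild", "RFD_mean", "chisq", "p")], 10),
          row.names = FALSE)
  } else {
    cat("  no significant windows\n")
  }
  invisible(x)
}

#' Plot a fixation selection scan
#'
#' One panel per chromosome: window mean RFD against window midpoint (cM),
#' with Bonferroni-significant windows highlighted. Positive RFD means
#' preferential fixation of the wild allele.
#'
#' @param x a [fixation_scan()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fixation_scan <- function(x, ...) {
  w <- x$windows
  if (nrow(w) == 0L) {
    warning("no windows to plot")
    return(invisible(x))
  }
  chroms <- unique(w$chrom)
  old <- graphics::par(mfrow = c(ceiling(length(chroms) / 2),
                                 min(2L, length(chroms))),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    mid <- (wc$start_cM + wc$end_cM) / 2
    graphics::plot(mid, wc$RFD_mean, type = "l", ylim = c(-1, 1),
                   xlab = "position (cM)", ylab = "window RFD",
                   main = ch, ...)
    graphics::abline(h = 0, lty = 3)
    if (any(wc$significant))
      graphics::points(mid[wc$significant], wc$RFD_mean[wc$significant],
                       col = "red", pch = 19)
  }
  invisible(x)
}
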