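#' Per-SNP wild-allele effects by simple linear regression
#'
#' For every SNP, fits an ordinary least-squares regression of the line
#' trait values on the wild-allele dosage (0/1/2) over complete pairs and
#' returns the slope: the estimated trait change per wild-allele copy.
#' SNPs with fewer than 3 complete pairs or constant dosage get a missing
#' effect.
#'
#' @param trait named numeric vector of line trait values (names = line
#'   identifiers), or a data frame with columns \code{line} and
#'   \code{value}.
#' @param dosage lines-by-SNPs dosage matrix (see [geno_to_dosage()]).
#' @return data frame with columns \code{snp}, \code{effect} (trait units
#'   per wild-allele copy) and \code{n} (complete pairs used).
#' @export
snp_effects <- function(trait, dosage) {
  if (is.data.frame(trait)) {
    if (!all(c("line", "value") %in% names(trait)))
      stop("trait data frame needs columns 'line' and 'value'")
    trait <- stats::setNames(trait$value, trait$line)
  }
  if (is.null(names(trait))) stop("'trait' must be named by line")
  lines <- intersect(rownames(dosage), names(trait))
  if (length(lines) < 3L) stop("fewer than 3 lines with trait data")
  y0 <- as.numeric(trait[lines])
  d <- dosage[lines, , drop = FALSE]
  eff <- rep(NA_real_, ncol(d))
  n <- integer(ncol(d))
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    ok <- !is.na(x) & !is.na(y0)
    n[j] <- sum(ok)
    if (n[j] < 3L) next
    vx <- stats::var(x[ok])
    if (vx == 0) next
    eff[j] <- stats::cov(x[ok], y0[ok]) / vx # OLS slope with intercept
  }
  data.frame(snp = colnames(d), effect = eff, n = n, row.names = NULL)
}

#' Correlation of fixation direction with SNP effects
#'
#' Pearson correlation, over SNPs with both values available, between
#' per-SNP wild-allele trait effects and relative fixation direction (RFD).
#' A positive correlation means alleles with larger wild-allele effects on
#' the trait were preferentially fixed toward the wild allele.
#'
#' @param effects data frame from [snp_effects()], or a named numeric
#'   vector of effects.
#' @param rfd named numeric vector of per-SNP RFD values, or the per-SNP
#'   data frame from [coef()] on a [fixation_scan()] fit.
#' @return list with \code{r} (Pearson correlation) and \code{n} (complete
#'   SNP pairs).
#' @export
rfd_effect_cor <- function(effects, rfd) {
  if (is.data.frame(effects))
    effects <- stats::setNames(effects$effect, effects$snp)
  if (is.data.frame(rfd))
    rfd <- stats::setNames(rfd$RFD, rfd$snp)
  snps <- intersect(names(effects), names(rfd))
  x <- as.numeric(effects[snps])
  y <- as.numeric(rfd[snps])
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 SNPs with both effect and RFD")
  list(r = stats::cor(x[ok], y[ok]), n = sum(ok))
}
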