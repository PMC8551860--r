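## Genotype coding used throughout the package:
##   0 = homozygous elite (recurrent-parent) allele
##   1 = heterozygous
##   2 = homozygous wild (donor) allele
##   NA = missing / failed call
## Matrices are lines x SNPs, with line identifiers as rownames, SNP
## identifiers as colnames, and an optional per-line family assignment in
## attr(, "family").

.GENO_LEVELS <- c(A = 0L, H = 1L, B = 2L)

#' Construct a genotype matrix
#'
#' Validates and annotates a lines-by-SNPs matrix of genotype calls coded
#' 0 (homozygous elite), 1 (heterozygous), 2 (homozygous wild), NA (missing).
#'
#' @param calls integer matrix, lines in rows (rownames = line identifiers),
#'   SNPs in columns (colnames = SNP identifiers).
#' @param family optional character vector of family labels, either named by
#'   line or in row order. When \code{NULL}, the prefix of each line
#'   identifier up to the first underscore is used.
#' @return the validated integer matrix with a \code{"family"} attribute.
#' @export
genotypes <- function(calls, family = NULL) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' must have line rownames and SNP colnames")
  if (anyDuplicated(rownames(calls))) stop("duplicated line identifiers")
  if (anyDuplicated(colnames(calls))) stop("duplicated SNP identifiers")
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad))
    stop("invalid genotype codes (expected 0, 1, 2 or NA) at ",
         sum(bad), " cells")
  if (is.null(family)) {
    family <- sub("_.*$", "", rownames(calls))
  } else {
    if (!is.null(names(family))) {
      if (!all(rownames(calls) %in% names(family)))
        stop("'family' names do not cover all lines")
      family <- unname(family[rownames(calls)])
    }
    if (length(family) != nrow(calls))
      stop("'family' must have one entry per line")
  }
  attr(calls, "family") <- as.character(family)
  calls
}

.family_of <- function(g, family = NULL) {
  fam <- if (is.null(family)) attr(g, "family") else family
  if (is.null(fam)) fam <- sub("_.*$", "", rownames(g))
  if (length(fam) != nrow(g)) stop("family assignment does not match lines")
  as.character(fam)
}

#' Convert genotype calls to wild-allele dosage
#'
#' Maps the four-state genotype coding to a quantitative SNP score: the
#' number of wild-allele copies (0 for homozygous elite, 1 for heterozygous,
#' 2 for homozygous wild; missing preserved).
#'
#' @param g genotype matrix (see [genotypes()]).
#' @return numeric lines-by-SNPs matrix of dosages.
#' @export
geno_to_dosage <- function(g) {
  d <- g
  attr(d, "family") <- NULL
  storage.mode(d) <- "double"
  d
}

#' Align two genotype matrices on shared lines and SNPs
#'
#' @param g0,g8 genotype matrices.
#' @return list with both matrices restricted to the shared line and SNP
#'   identifiers, in the order of \code{g0}.
#' @keywords internal
align_genotypes <- function(g0, g8) {
  lines <- intersect(rownames(g0), rownames(g8))
  snps <- intersect(colnames(g0), colnames(g8))
  if (length(lines) == 0L) stop("no shared line identifiers")
  if (length(snps) == 0L) stop("no shared SNP identifiers")
  fam <- .family_of(g0)[match(lines, rownames(g0))]
  list(g0 = genotypes(g0[lines, snps, drop = FALSE], fam),
       g8 = genotypes(g8[lines, snps, drop = FALSE], fam))
}
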