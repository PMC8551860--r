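## File formats. The canonical interchange for genotype calls is a TSV with
## line identifiers in the first column ("line") and one column per SNP,
## cells coded A (homozygous elite) / H (heterozygous) / B (homozygous
## wild) / NA, or -1/0/1/NA in the numeric dialect. The genetic map is a
## TSV with columns snp, chrom, cM.

#' Read a genotype matrix from TSV
#'
#' @param path file path.
#' @param dialect \code{"letters"} for A/H/B calls or \code{"numeric"} for
#'   -1/0/1 (elite/het/wild).
#' @param family optional per-line family assignment (named vector); by
#'   default the line-identifier prefix up to the first underscore.
#' @return genotype matrix (see [genotypes()]).
#' @export
read_geno_tsv <- function(path, dialect = c("letters", "numeric"),
                          family = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (ncol(df) < 2L || names(df)[1L] != "line")
    stop("expected a 'line' column followed by SNP columns in ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicated line identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  codes <- if (dialect == "letters") .GENO_LEVELS else
    c(`-1` = 0L, `0` = 1L, `1` = 2L)
  bad <- !is.na(m) & !(m %in% names(codes))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown genotype symbol '%s' at line %s, SNP %s in %s",
                 m[bad][1L], ids[w[1L]], colnames(m)[w[2L]], path))
  }
  g <- matrix(codes[m], nrow(m), ncol(m), dimnames = dimnames(m))
  genotypes(g, family)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_geno_tsv()] (letters dialect).
#'
#' @param g genotype matrix.
#' @param path output file path.
#' @export
write_geno_tsv <- function(g, path) {
  sym <- names(.GENO_LEVELS)[match(g, .GENO_LEVELS)]
  m <- matrix(sym, nrow(g), ncol(g), dimnames = dimnames(g))
  df <- data.frame(line = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map from TSV
#'
#' @param path TSV with columns \code{snp}, \code{chrom}, \code{cM}.
#' @return validated, ordered map (see [check_map()]).
#' @export
read_map_tsv <- function(path) {
  check_map(utils::read.delim(path, check.names = FALSE))
}

#' Write a genetic map to TSV
#' @param map genetic map.
#' @param path output file path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(check_map(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trait table from TSV
#'
#' @param path TSV with columns \code{line}, \code{trait}, \code{value}.
#' @return data frame with those columns.
#' @export
read_trait_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("line", "trait", "value") %in% names(df)))
    stop("trait TSV needs columns line, trait, value")
  df$value <- as.numeric(df$value)
  df
}

#' Import genotype calls from a VCF
#'
#' Converts biallelic GT calls to the four-state coding: 0/0 to homozygous
#' elite (REF is taken as the elite allele), 0/1 or 1/0 to heterozygous,
#' 1/1 to homozygous wild, ./. to missing; phased separators are treated
#' like unphased. Multi-allelic sites are dropped with a warning. Requires
#' the \pkg{vcfR} package.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param family optional per-line family assignment.
#' @return genotype matrix (lines = samples, SNPs = sites).
#' @export
read_vcf_geno <- function(path, family = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) dropped: ",
            paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(gt) <- ids
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    bad <- !is.na(x) & is.na(out) & !(x %in% c("./.", "."))
    if (any(bad)) stop("unsupported GT value: ", x[bad][1L])
    out
  }
  g <- apply(gt, 2L, code)
  g <- matrix(g, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  genotypes(t(g), family)
}

#' Write selection-scan outputs
#'
#' Writes the standard result files for a fitted scan under a common
#' prefix: the fixation matrix (\code{<prefix>_fixation.tsv}, values
#' -1/0/1/NA), the per-SNP summary (\code{<prefix>_snps.tsv}), the window
#' tests (\code{<prefix>_windows.tsv}), a BED-like track of window
#' intervals in cM coordinates (\code{<prefix>_track.bed}: chrom, start cM,
#' end cM, window RFD, p, significant) and a JSON run manifest
#' (\code{<prefix>_manifest.json}). Outputs are deterministic: identical
#' fits yield byte-identical files.
#'
#' @param scan a [fixation_scan()] object.
#' @param prefix output path prefix.
#' @param config optional named list recorded in the manifest (seeds,
#'   thresholds, input paths).
#' @return invisibly, the vector of files written.
#' @export
write_scan_outputs <- function(scan, prefix, config = NULL) {
  if (!inherits(scan, "fixation_scan"))
    stop("'scan' must come from fixation_scan()")
  num <- function(d) {
    for (j in seq_along(d)) if (is.numeric(d[[j]]))
      d[[j]] <- signif(d[[j]], 6)
    d
  }
  fm <- scan$fixation
  fdf <- data.frame(line = rownames(fm), unclass(fm)[, , drop = FALSE],
                    check.names = FALSE)
  files <- c(fixation = paste0(prefix, "_fixation.tsv"),
             snps = paste0(prefix, "_snps.tsv"),
             windows = paste0(prefix, "_windows.tsv"),
             track = paste0(prefix, "_track.bed"),
             manifest = paste0(prefix, "_manifest.json"))
  utils::write.table(fdf, files["fixation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(num(scan$snp), files["snps"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(num(scan$windows), files["windows"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  w <- scan$windows
  track <- data.frame(chrom = w$chrom, start = signif(w$start_cM, 6),
                      end = signif(w$end_cM, 6),
                      RFD = signif(w$RFD_mean, 6), p = signif(w$p, 6),
                      significant = as.integer(w$significant))
  utils::write.table(track, files["track"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(package = "fixscan",
                   version = as.character(utils::packageVersion("fixscan")),
                   parameters = list(window = scan$window, step = scan$step,
                                     alpha = scan$alpha,
                                     min_het = scan$min_het),
                   n_lines = scan$n_lines, n_snps = scan$n_snps,
                   n_testable_windows = scan$n_testable,
                   config = config)
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(files)
}
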