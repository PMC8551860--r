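#' Validate and order a genetic map
#'
#' A genetic map is a data frame with columns \code{snp} (unique SNP
#' identifiers), \code{chrom} (chromosome label, e.g. "1H") and \code{cM}
#' (genetic position in centiMorgan, non-negative). Ordering is by
#' chromosome (first-appearance order), then position, with ties broken by
#' SNP identifier for determinism.
#'
#' @param map data frame with columns \code{snp}, \code{chrom}, \code{cM}.
#' @return the map, ordered, with character \code{snp}/\code{chrom} columns.
#' @export
check_map <- function(map) {
  if (!is.data.frame(map) || !all(c("snp", "chrom", "cM") %in% names(map)))
    stop("'map' must be a data frame with columns snp, chrom, cM")
  if (nrow(map) == 0L) stop("'map' is empty")
  map$snp <- as.character(map$snp)
  map$chrom <- as.character(map$chrom)
  map$cM <- as.numeric(map$cM)
  if (anyDuplicated(map$snp)) stop("duplicated SNP identifiers in map")
  if (anyNA(map$cM) || any(map$cM < 0)) stop("map positions must be >= 0")
  chrom_rank <- match(map$chrom, unique(map$chrom))
  map[order(chrom_rank, map$cM, map$snp), , drop = FALSE]
}

## Split an ordered map into per-chromosome segments. Positions are shifted
## to start at 0; 'len' is the cM span used as the expected-crossover scale.
.map_segments <- function(map) {
  lapply(split(seq_len(nrow(map)), factor(map$chrom, unique(map$chrom))),
         function(idx) {
           pos <- map$cM[idx]
           list(idx = idx, pos = pos - min(pos),
                len = max(pos) - min(pos))
         })
}

#' Build an evenly spaced synthetic genetic map
#'
#' @param n_snps total number of SNPs, distributed as evenly as possible
#'   over the chromosomes.
#' @param n_chrom number of chromosomes (labelled "1H", "2H", ... as in
#'   barley).
#' @param chrom_length chromosome length in cM (recycled over chromosomes).
#' @return genetic map data frame (see [check_map()]).
#' @export
sim_genetic_map <- function(n_snps, n_chrom = 7, chrom_length = 150) {
  if (n_snps < 1 || n_chrom < 1) stop("'n_snps' and 'n_chrom' must be >= 1")
  chrom_length <- rep_len(chrom_length, n_chrom)
  per <- diff(floor(seq(0, n_snps, length.out = n_chrom + 1)))
  rows <- lapply(seq_len(n_chrom), function(c) {
    k <- per[c]
    if (k == 0L) return(NULL)
    data.frame(snp = sprintf("snp_%d_%03d", c, seq_len(k)),
               chrom = paste0(c, "H"),
               cM = seq(0, chrom_length[c], length.out = max(k, 2L))[seq_len(k)])
  })
  check_map(do.call(rbind, rows))
}
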