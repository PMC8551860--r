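# Shared fixtures, built in code.

# Tiny genotype matrix from a coded vector/matrix; lines F<fam>_<i>.
toy_geno <- function(calls, n_lines = nrow(calls), families = NULL) {
  m <- as.matrix(calls)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("F%02d_%03d",
                           if (is.null(families)) rep(1L, nrow(m)) else families,
                           seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  genotypes(m)
}

# Random paired genotype matrices with known coding, for oracle checks.
rand_pair <- function(n_lines, n_snps) {
  g0 <- matrix(sample(c(0L, 1L, 2L, NA), n_lines * n_snps, TRUE,
                      prob = c(0.35, 0.3, 0.25, 0.1)),
               n_lines, n_snps,
               dimnames = list(sprintf("F01_%03d", seq_len(n_lines)),
                               sprintf("s%03d", seq_len(n_snps))))
  g8 <- matrix(sample(c(0L, 1L, 2L, NA), n_lines * n_snps, TRUE,
                      prob = c(0.3, 0.25, 0.3, 0.15)),
               n_lines, n_snps, dimnames = dimnames(g0))
  list(g0 = genotypes(g0), g8 = genotypes(g8))
}

# Single-chromosome map with given positions.
mini_map <- function(cM, chrom = "1H", snp = sprintf("s%03d", seq_along(cM))) {
  check_map(data.frame(snp = snp, chrom = chrom, cM = cM))
}

# Plant genome helpers for the simulator tests.
plant_hom <- function(n, allele = 0L) list(hap1 = rep(allele, n),
                                           hap2 = rep(allele, n))
plant_het <- function(n) list(hap1 = rep(0L, n), hap2 = rep(1L, n))
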