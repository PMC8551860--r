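Package: fixscan
Title: Selection Scans from Temporal Fixation of Residual Heterozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects loci under selection in partially inbred crop populations
    by tracking the fate of residual heterozygosity between two generations of
    the same lines. Given paired SNP genotype matrices for an early generation
    (single genotyped plants) and a later generation (pooled-progeny calls),
    the package computes per-SNP allele fixation rates (AFR) and relative
    fixation directions (RFD), scans the genome with sliding-window chi-square
    goodness-of-fit tests against the neutral 1:1 fixation ratio under
    Bonferroni control, and relates fixation direction to per-SNP trait
    effects. Analytic selfing-segregation expectations and a binomial
    pooled-sampling bias simulation quantify how much fixation is expected
    without selection, and a forward simulator of backcross-derived nested
    association mapping (NAM) populations generates paired matrices with
    known ground truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
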