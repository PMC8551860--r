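# fixscan

Selection scans from the temporal fixation of residual heterozygosity in
partially inbred plant populations.

## The problem

Large experimental crop populations — composite crosses, MAGIC and nested
association mapping (NAM) populations — are maintained for years by selfed
field propagation. Lines of a backcross-derived NAM population
(BC1S3-derived) still segregate at a predictable fraction of loci: a BC1S3
plant is expected to be 71.875% homozygous for the elite (recurrent-parent)
allele, 6.25% heterozygous, and 21.875% homozygous for the wild (donor)
allele. During further propagation that residual heterozygosity decays —
halving per selfing generation, with a quarter fixing into each homozygous
class — and *which* homozygous class it fixes into is informative: under
neutrality elite- and wild-allele fixation are equally likely, so a
directional excess at a locus is a footprint of natural selection
(plant–plant competition) or artificial selection (harvesting practice)
during population maintenance.

`fixscan` is for quantitative geneticists and genebank curators who have SNP
genotypes for the same lines at two generations — single plants early,
pooled progeny later — and want to locate loci under selection.

## The statistics

For each SNP, over the lines that were heterozygous in the early generation
(`g0`), the later-generation (`g8`) call is recoded as a fixation value:
−1 (fixed homozygous elite), 0 (heterozygosity retained in the pool), +1
(fixed homozygous wild), NA (missing). Then, with `n_het0` the number of
initially heterozygous lines at the SNP:

- **AFR** (allele fixation rate) = (#fixed calls) / `n_het0` ∈ [0, 1]
- **RFD** (relative fixation direction) = (#wild-fixed − #elite-fixed) /
  `n_het0` ∈ [−1, 1]; positive = wild allele favoured.

A sliding window of 10 consecutive SNPs (step 1, within chromosomes) sums
the elite- and wild-fixed counts and tests them against the neutral 1:1
ratio with a 1-df chi-square goodness-of-fit statistic,
χ² = (n_elite − n_wild)² / (n_elite + n_wild), flagging windows at a
Bonferroni-corrected p < 0.01.

Around the scan the package provides the analytic selfing expectations
(`selfing_segregation`), a binomial simulation of pooled-sampling bias
(`pool_bias_sim`: the probability that a pool of 12 plants is spuriously
called homozygous), marker/line QC filters with the standard thresholds
(`qc_pipeline`), per-SNP trait-effect regression and its correlation with
RFD (`snp_effects`, `rfd_effect_cor`), and a forward simulator of the whole
experimental design with known ground truth (`sim_heb_experiment`).

## Worked example

Simulate a 25-family NAM experiment (300 lines, 300 SNPs on 3 chromosomes)
with one viability-selected wild locus on chromosome 2H, run QC and fit the
scan:

```r
library(fixscan)
map <- sim_genetic_map(300, n_chrom = 3)
sel <- selection_model("snp_2_050", s = 1.5, h = 0.5, phase = "viability")
sim <- sim_heb_experiment(map, n_families = 25, lines_per_family = 12,
                          selection = sel, seed = 2024)
qc  <- qc_pipeline(sim$g0, sim$g8, map)
fit <- fixation_scan(qc$g0, qc$g8, map)
summary(fit)
```

```
Temporal fixation selection scan
  300 lines, 300 SNPs (293 with >= 10 initially heterozygous lines)
  pooled fixation fraction: 0.297   mean per-SNP AFR: 0.297
  windows: 266 (266 testable), Bonferroni alpha = 0.01 -> p < 3.76e-05
  significant windows: 45
  mean per-SNP RFD (scanned SNPs): 0.0482

Significant windows (strongest first):
 chrom start_cM   end_cM n_elite n_wild  RFD_mean    chisq            p
    2H 66.66667 80.30303       2     97 0.6539054 91.16162 1.324039e-21
    2H 68.18182 81.81818       3     97 0.6353534 88.36000 5.456307e-21
    ...
```

The strongest windows sit on 2H around 66–85 cM and cover the selected
locus (`snp_2_050` at 74.2 cM); their positive mean RFD (~0.65) says the
wild allele was fixed preferentially there, and the pooled fixation
fraction (~0.30) shows how much apparently fixed genotype a neutral
background already produces through drift and pooled calling —
which is why the scan works on *direction*, not on the fixation rate
alone. `plot(fit)` draws the per-chromosome RFD tracks with significant
windows highlighted, and `write_scan_outputs(fit, "results/run1")` writes
the fixation matrix, per-SNP and window tables, a BED-like cM track and a
JSON manifest.

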