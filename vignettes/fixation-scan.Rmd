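---
title: "Detecting selection from the fixation of residual heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection from the fixation of residual heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixscan)
```

## The model

`fixscan` analyses temporal SNP data from a partially inbred population:
the same lines genotyped once as single plants in an early generation
(`g0`) and again, after several seasons of selfed field propagation, as a
pooled DNA sample of their progeny (`g8`). The biological object of
interest is the fate of *residual heterozygosity* — the loci still
segregating within a line in `g0`.

Under self-fertilisation without selection, the heterozygote fraction at a
locus halves every generation and a quarter of it fixes into each
homozygous class:

$$ (p_{AA}, p_{Aa}, p_{aa})_{n} =
   \Big(p_{AA} + p_{Aa}\tfrac{1-2^{-n}}{2},\;
        p_{Aa}\,2^{-n},\;
        p_{aa} + p_{Aa}\tfrac{1-2^{-n}}{2}\Big). $$

`selfing_segregation()` implements this recursion. Two anchor points
organise the whole analysis: a backcross-derived BC1S3 plant (the BC1
distribution (0.5, 0.5, 0) taken through three selfings) is expected at
(0.71875, 0.0625, 0.21875), and an initially heterozygous locus taken
through five further selfings is expected at (0.484375, 0.03125,
0.484375). The essential point is the *symmetry* of that endpoint: under
neutrality, fixation toward either homozygous class is equally likely.

For every `g0`-heterozygous line × SNP entry the later call is recoded as
a fixation value: −1 (fixed elite), 0 (heterozygosity reconstructed in the
pool), +1 (fixed wild), NA (missing); entries not initially heterozygous
are masked and never counted. Per SNP, with $n_{het0}$ initially
heterozygous lines, $n_{Hv}$ elite-fixed and $n_{Hsp}$ wild-fixed lines:

$$ \mathrm{AFR} = \frac{n_{Hv} + n_{Hsp}}{n_{het0}}, \qquad
   \mathrm{RFD} = \frac{n_{Hsp} - n_{Hv}}{n_{het0}}. $$

AFR measures how fast heterozygosity was lost; RFD measures which allele
won. A 10-SNP sliding window (step 1, never crossing a chromosome
boundary) sums the fixed-allele counts and tests them against 1:1 with
$\chi^2 = (n_{Hv} - n_{Hsp})^2 / (n_{Hv} + n_{Hsp})$ on 1 df; windows are
declared significant at a Bonferroni-corrected level, $p < \alpha /
(\text{number of testable windows})$, with $\alpha = 0.01$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 10 SNPs | SNPs summed per window; matches the window the method was designed with |
| `step` | 1 SNP | fully overlapping windows; "sliding" in the conventional sense |
| `alpha` | 0.01 | family-wise level before Bonferroni division by testable windows |
| `min_het` | 10 lines | SNPs with fewer initially heterozygous lines are summarised but excluded from the scan (small denominators make AFR/RFD unstable) |
| `max_failure` | 0.10 | QC: strict upper bound on missing-call fraction |
| `max_het` | 0.125 | QC: strict upper bound on heterozygous fraction (twice the early-generation expectation) |
| `max_mismatch` | 0.05 | QC: lines whose `g0`-homozygous SNPs flip to the opposite homozygote at a higher rate are treated as mislabelled |
| `pool_size` | 12 plants | plants pooled for later-generation DNA |
| `minor_tolerance` | 0.2 | minor-allele fraction up to which a pooled call is still homozygous, mimicking the calling tolerance of two-channel arrays |

Decisions the method description leaves open, resolved here as package
defaults: the window step (1), the Bonferroni denominator (testable
windows, since the tests are per-window), windows with zero fixed alleles
(untestable, excluded from that denominator), the heterozygosity-rate
denominator in QC (non-missing calls; missingness has its own rule),
duplicate-column ties (keep the first in map order), map-position ties
(broken by SNP identifier), and the mismatch metric for line consistency
(opposite-homozygote rate at `g0`-homozygous SNPs — changes selfing cannot
produce). Missing later calls stay in the AFR/RFD denominators by default,
reading the definitions literally (the denominator counts `g0`
heterozygotes); `complete_pairs = TRUE` switches to complete-pair
denominators. Because the genome-wide mean AFR can be formed two ways, the
fitted object reports both `mean_afr` (mean of per-SNP AFRs over scanned
SNPs) and `pooled_afr` (all fixed calls over all initially heterozygous
calls).

## Expected fixation without selection

Two neutral yardsticks calibrate observed fixation.

**Pooled-sampling bias.** Even a line still segregating at the expected
0.484375 : 0.03125 : 0.484375 can yield a homozygous call if the sampled
pool happens to be one-sided. `pool_bias_sim()` draws each of the
`pool_n = 12` plants independently into one homozygous class with
probability `p_seg` and thresholds the same-class count at `k_call`,
estimating the spurious-call probability per allele class over
`n_trials` pools (default 10^6), alongside the exact binomial tail
`pool_bias_exact()`. At `p_seg = 0.484375`: all-12 sampling has
probability ≈ 0.017% (< 0.2%) per class; with the array's ~20% calling
tolerance (≥ 9 of 12 plants) it rises to ≈ 5.9% (< 6%) per class. Both
thresholds are exposed because the assay tolerance (~20% minor allele, i.e.
≤ 2 of 12 plants) and the simulated ≥ 9-of-12 rule imply different
cutoffs; which one a given array realises depends on its cluster
calibration. `pool_bias_grid()` sweeps segregations 0.05–0.95 (default
step 0.05).

**Drift.** Sampling bias is not the only neutral source of fixation: the
propagation design itself (20 harvested ears founding each next season)
is a recurring bottleneck, and the forward simulator (below) shows that
drift plus calling tolerance produces a genome-wide neutral AFR far above
the binomial yardstick — symmetric in direction, hence invisible to RFD.
This is why the scan tests *direction*, not rate.

## The forward simulator

`sim_heb_experiment()` generates paired matrices with known ground truth,
emulating the experimental design end to end:

1. **Founders** (`sim_founders`): one fully inbred elite recurrent parent;
   `n_families` (default 25) fully inbred wild donors, each polymorphic at
   an independent random subset of SNPs (`wild_polymorphism_rate`,
   default 1 — the genotyping panel is ascertained for elite × wild
   polymorphism; lower it to exercise the per-family polymorphism QC rule).
2. **Line creation** (`sim_bc1s3`): F1 = donor × elite, one backcross to
   the elite parent, three selfings by single-seed descent; the resulting
   plants are genotyped perfectly into `g0`.
3. **Propagation** (`propagate_line`): per season, sow `n_sown` selfed
   seeds pooled from the previous season's mother plants, then harvest
   `n_ears` mothers without replacement with probability proportional to
   fitness. The default schedule sows (60, 60, 60, 100, 20) plants with 20
   ears harvested per non-final season — the experiment's stated seed
   counts, with the unreported first-season plot size set to 60 — giving
   exactly five selfing generations.
4. **Selection** (`selection_model`): per-locus fitness 1, 1 + hs, 1 + s
   (elite hom / het / wild hom), multiplicative across loci. The sources of
   selection named for such experiments — plant–plant competition
   ("viability") and harvesting practice ("harvest") — share this
   functional form; both phases act as weights on which plants become
   mothers, because the number of sown plants surviving to harvest is not
   reported and a separate survival bottleneck would add an unidentifiable
   parameter.
5. **Pooled calling** (`pool_and_call`): sample `pool_size` plants from the
   final cohort, call each SNP homozygous when the minor-allele fraction is
   at most `minor_tolerance`, heterozygous otherwise, missing with
   probability `failure_rate`.

Recombination uses the standard no-interference model: per chromosome, a
Poisson crossover count with mean cM-span/100 and uniform positions
(Haldane). Internally, propagation tracks only the loci still heterozygous
in each line's genotyped plant — all other loci are invariant under
selfing — which is what makes simulating hundreds of lines by plant-level
forward simulation cheap.

What the simulator does *not* emulate: mutation, outcrossing, seed
dormancy and carry-over, shared polymorphism structure between families
(masks are independent), fluorescence-level array physics (only the
count-threshold abstraction), and environment-dependent phenology. Passing
tests on simulated data therefore show that the statistics recover what
this design generates, not that any particular real locus is under
selection.

## Calibration of the neutral null, and a caveat inherited from the method

With perfect calling — the whole final cohort pooled, zero tolerance, no
failures — a neutral simulation at 500 lines × 2,000 SNPs yields a mean
RFD within Monte-Carlo noise of zero and a Bonferroni-significant window
fraction below 1% (the package's acceptance tests run exactly this, with
chromosome means used as independent replicates for the standard error of
the genome mean).

Under the *default* pooled caller (12 plants, 20% tolerance) the same
neutral simulation shows AFR ≈ 0.2 genome-wide and flags ~14% of windows.
Both effects are real properties of the data-generating process, not of
the implementation: drift through the 20-ear bottlenecks spreads within-
line allele frequencies away from ½ so the tolerant caller fixes many of
them (symmetrically), and the window statistic sums counts from 10 tightly
linked SNPs whose fixation events are strongly correlated within lines,
while the 1-df reference distribution treats them as independent. The
window test is implemented exactly as the method prescribes; users should
read window p-values as a ranking device and rely on the Bonferroni flag
plus effect direction, replication across neighbouring windows, and the
neutral simulator for calibration at their own design parameters.

## Trait-effect association

`snp_effects()` regresses line-level trait values on wild-allele dosage
(0/1/2) per SNP — a univariate OLS slope over complete pairs, estimated on
whichever lines have data, with no family covariates (a literal "simple
linear model"; SNPs with constant dosage or fewer than 3 pairs are
missing). `rfd_effect_cor()` then reports the Pearson correlation between
those effects and RFD: a positive correlation means wild alleles that
increase the trait were preferentially fixed, the signature of selection
acting through that trait (e.g. taller plants competing better or being
harvested preferentially).

## Numerical and degenerate-input choices

Chi-square without continuity correction (the plain goodness-of-fit test);
SNPs with a zero AFR/RFD denominator get NA statistics; windows need
`window` SNPs on the chromosome, otherwise the chromosome contributes no
windows; genotype readers reject unknown symbols and duplicate identifiers
rather than coercing; pooled calls with a tied allele count are
heterozygous (the minor fraction is 0.5, above any valid tolerance);
multi-allelic VCF sites are dropped with a warning. All simulator
randomness flows from a single seed, and identical configurations produce
byte-identical outputs including the written result files.

## Problem sizes used by the test suite

The packaged tests run the neutral null at 500 lines × 2,000 SNPs (one
run) and the selected-locus recovery at 250 lines × 100 SNPs (100
replicates, one viability-selected wild locus at s = 1), sizes chosen to
make the Monte-Carlo bounds sharp while keeping the default suite around
three minutes; distributional checks (segregation proportions, Haldane
recombination fractions, selfing expectations under propagation) use
1,000–8,000 replicates with 3-standard-error bands.

## Limitations

The scan assumes the two matrices describe the same lines (the QC
mismatch filter catches gross errors only); it cannot separate natural
from artificial selection — only the simulator's labelled phases can, and
only in simulation; window p-values are anti-conservative under linkage
(above); and AFR-based inferences are sensitive to the pooled-calling
tolerance, which is an assay property users should measure or bound, not a
biological constant.
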