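---
title: "riceeco: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riceeco: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`riceeco` re-implements, at desk scale, the population-genomic toolchain used
to study how cultivated rice ecotypes (deepwater, upland, rainfed lowland,
irrigated, swamp, tidal wetland) diverged from their wild and cultivated
progenitors:

* **Windowed nucleotide diversity** ($\theta_\pi$): per site
  $\pi_s = 2 c_{\mathrm{ref}} c_{\mathrm{alt}} / (n (n-1))$ over the $n$
  non-missing alleles, summed per window and divided by the window length in
  bp (the VCFtools `--window-pi` convention — invariant bases count in the
  denominator). Default grid: 100-kb windows, 50-kb step.
* **Weir–Cockerham $F_{ST}$** (1984 variance components $a, b, c$ from
  per-site sample sizes, allele frequencies and observed heterozygote
  frequencies), combined per window as the weighted ratio of sums
  $\sum a / \sum (a+b+c)$. Negative estimates are reported as-is. A Hudson
  estimator is available behind `estimator = "hudson"` for sensitivity
  analysis.
* **ROD** (reduction of diversity): $\pi_{\mathrm{ancestral}} /
  \pi_{\mathrm{derived}}$ per window, the classic domestication-sweep scan.
* A **composite multi-signature sweep score** (diversity deficit +
  site-frequency-spectrum distortion + LD block structure, each as a
  genome-wide rank-based normal score) on a non-overlapping 50-kb grid. This
  is an explicitly declared stand-in for $\mu$-statistic-style scanners, not
  a re-implementation of any of them; its contract is planted-signal
  recovery, not tool parity.
* **Top-1% outlier region calling** with merging of overlapping or bookended
  windows, gene annotation by half-open interval overlap, and genome-fraction
  reporting.
* **Standing / new / lost variant classification** between an ecotype and its
  immediate ancestral progenitor, with alternative-allele-frequency
  differentiation (AFD) summaries.
* An **EMMAX-style linear mixed model GWAS** on the binary ecotype phenotype
  (target ecotype = 1, everything else = 0), with PLINK-style
  `--indep-pairwise 50 5 0.3` LD pruning, the suggestive threshold
  $-\log_{10}(\alpha / n_{\mathrm{indep}})$, PC covariates and distance-based
  QTL clumping.
* A **candidate-gene screen**: the two-ratio RPKM rule
  (deepwater/non-deepwater and after/before submergence, both $> 1.5$ for
  "up" or both $< 0.67$ for "down") plus pseudo-haplotype differentiation
  across groups with a permutation chi-square test.

Everything runs end-to-end on a bundled forward Wright–Fisher simulator, so
each claim the package makes is checked against planted ground truth.

# The simulator's stated world

`sim_config()` fixes one demography: a wild population of $N$ diploids at
mutation–drift equilibrium (burn-in $\ge 8N$ generations), a progenitor
founded from it through a bottleneck (default 50 founders for 20
generations), and a derived ecotype founded from the progenitor through the
same bottleneck shape. Mutation (infinite sites) continues after the splits;
these post-split variants populate the "new mutation" truth class.
Reproduction is Wright–Fisher with partial selfing.

Key defaults, with reasons:

| parameter | default | why |
|---|---|---|
| genome | 2 chromosomes × 2 Mb | desk-scale; explicitly not genome scale |
| $N$ (all populations) | 200 diploids | large enough for stable window statistics, small enough for seconds-scale runs |
| emitted accessions | 40 per population | panel-sized groups comparable to real ecotype panels |
| $\mu$ | $2.5 \times 10^{-7}$ /bp/gen | gives wild $\theta = 4N\mu = 2\times10^{-4}$/bp — about one tenth of real rice diversity, so SNP counts stay desk-sized |
| $c$ (crossover rate) | $1 \times 10^{-6}$ /bp/gen | keeps the rice-like $c/\mu \approx 4$ ratio, so windows are quasi-independent genealogies as they are in a real genome. A mis-scaled $c$ makes window diversity pure drift noise |
| selfing rate | 0.99 | rice landraces are near-inbred; heterozygotes are rare but present, keeping het-handling paths exercised |
| missing rate | 0.02 | typical post-filter missingness |
| sweeps | two 100-kb loci, strength 5 | the scan targets |

**Sweep mechanism.** Sweeps are planted, not selected for: over the last
$0.2N$ generations one donor haplotype's window segment is driven along a
deterministic logistic trajectory to frequency $f = \sqrt{1 - 1/s}$, where
$s$ is `sweep_strength`; pairwise diversity in the window then falls by
$\approx 1 - f^2 = 1/s$. Conversion copies an actual carrier's *current*
window segment, so post-planting mutations on the swept background hitchhike
as they would under real linkage. A locus with no segregating site at
planting time cannot define a donor; the sweep is skipped and recorded as
such in the truth table.

**Randomness.** One master seed; every stage (engine, missingness, Q values,
phenotype, expression) draws from its own derived stream
(`derive_seed(seed, stage)`), so adding a stage never perturbs another. The
engine uses its own Mersenne Twister with hand-rolled uniform and Poisson
draws, so runs are bit-identical across platforms; `std::poisson_distribution`
is implementation-defined and deliberately avoided.

**What a green test does and does not establish.** The simulator reproduces
the *relative* structure the analysis assumes — diversity ratios between
populations, bottleneck-depressed progenitor diversity, sweep troughs, LD
decay, near-homozygosity, a truth table for recovery rates. It does not
reproduce rice's absolute diversity, recombination landscape, real linkage
disequilibrium blocks, gene conversion, or selection on standing variation;
a green recovery test therefore says the scan finds the signal its theory
predicts at this scale, not that real-data counts (26/30/49 sweeps, 28 QTLs,
20 candidates) would be reproduced. Those require the original panels.

**Neutral calibration.** The equilibrium expectation $\pi = 4N\mu$ holds
under random mating, so the calibration test runs the engine with
`selfing_rate = 0`; with selfing $s$ the effective size shrinks to
$N/(1+F)$, $F = s/(2-s)$, and the default 0.99 world sits near $\theta/2$.

# Numerical and convention choices

* **MAF** is computed over non-missing called alleles only; a variant with no
  calls has undefined MAF and is dropped by the filter. Boundary values are
  kept (missing $\le$ 0.5, MAF $\ge$ 0.05, as printed); the ancestry filter
  is strict ($Q > 0.8$).
* **Coordinates.** VCF positions are 1-based; BED and all window/region
  intervals are 0-based half-open. A gene abutting a region boundary does not
  overlap it.
* **ROD orientation** is the literal ratio $\pi_{anc}/\pi_{der}$ ranked on
  its upper tail (not $1 - \pi_{der}/\pi_{anc}$). Windows with zero derived
  diversity are floored at $\varepsilon$ = the 1st-percentile order statistic
  of the positive derived values and flagged; windows with zero ancestral
  diversity are undefined and excluded from ranking. The order-statistic
  (type-1) quantile is used so the floor never distorts positive values.
* **Outlier threshold.** Top 1% means the `floor((1-q) M)` highest windows
  (at least one), with ties at the threshold value included. Merging joins
  overlapping *and* bookended windows, so the sliding windows of one sweep
  collapse into a single region.
* **Allele-frequency convention.** The default is alt/(alt+ref), which lives
  in [0, 1]; the literal "ratio of alternative to reference alleles"
  (alt/ref) is kept behind `convention = "odds"` because summaries under that
  reading exceed 1 and cannot match 0–1 scale reports. Because published
  per-class headline numbers are ambiguous between mean AFD and mean alt
  frequency, `afd_summary()` emits both.
* **Variant presence** for standing/new/lost classification means alt-allele
  count $\ge$ `min_carrier_count` (default 1). Singleton-driven "new" calls
  are sequencing-error-sensitive on real data, so the threshold is exposed.
  A variant uncalled in one whole population is classified from the other
  population alone and flagged, never silently labelled.
* **Mixed model.** The binary phenotype is treated as quantitative (a linear,
  not logistic, mixed model) — mirroring common FaST-LMM usage and documented
  as an approximation. $\delta = \sigma^2_e/\sigma^2_g$ is estimated once by
  REML on the covariate-only null (grid over $\log_{10}\delta \in [-5, 5]$,
  then Brent refinement — golden-section plus parabolic steps — to $10^{-6}$)
  and reused for every SNP (the EMMAX approximation). With $K = I$ the scan
  reduces exactly to OLS, which the tests assert to $10^{-8}$.
* **LD pruning** slides the 50-SNP window over the *surviving* SNP list and
  repeats to a fixed point. Removal picks the lower-MAF member of the worst
  pair, ties broken toward the later position; r² is the squared Pearson
  correlation of dosages over pairwise-complete samples. The fixed-point form
  guarantees the exhaustive post-hoc scan property and idempotence.
* **QTL clumping** uses single-linkage at 200 kb (no clumping rule is printed
  with the 28-signal count; 200 kb ≈ two window sizes, exposed as a flag).
* **PC covariates** are computed on the pruned SNP set by default (flag to
  use all SNPs); sign is fixed by making each component's largest-magnitude
  loading positive.
* **Pseudo-haplotypes** come from unphased diploid codes, justified by
  near-complete homozygosity; het or missing sites are filled with the
  region-wide major allele when an accession's het+missing fraction is
  $\le$ 0.2, otherwise the accession is dropped. The haplotype region is the
  gene body with a configurable flank (the published analysis does not state
  its SNP set). The differentiation test is a Pearson chi-square with a
  group-label permutation p-value, since no test is named; Fisher's exact
  test would also be defensible for small tables.
* **Expression rule.** Direction must be consistent across both ratios (both
  $> 1.5$ or both $< 0.67$, strict); all-four-zero genes are "excluded"
  (unexpressed retrotransposon-like genes); a zero denominator with positive
  numerator counts as exceeding the upper cut and is flagged infinite.

# Known limitations

* The composite sweep score is a stand-in with an honest scale limitation:
  in a small bottlenecked ecotype, drift alone produces windows that mimic
  all three of its signatures, so its planted-sweep recovery at desk scale
  trails the ROD scan's on the same replicates (both rates are computed by
  the acceptance suite). At real-rice effective sizes drift cannot produce
  such troughs; the limitation is the price of the scaled-down world, and the
  acceptance criterion is asserted unweakened.
* Small-panel GWAS fixtures confound family relatedness with oligogenic
  signal: with ~10² accessions from a desk-scale population, even unlinked
  loci are correlated through shared ancestry, LD pruning collapses thousands
  of SNPs to a few dozen effective tests, and the kinship/PC corrections
  partially absorb a trait driven by three planted SNPs. The recovery
  experiment therefore uses a deliberately unstructured single-population
  panel and plants causal triples whose marginal effects cannot cancel; its
  measured recovery rate is computed (not assumed) by the acceptance suite.
* The two published GWAS SNP counts for the same filter (2,282,266 vs
  2,317,387) cannot both be right; the package applies the stated filter and
  reports its own counts.
* Windowed $F_{ST}$ weighting (weighted ratio-of-sums vs mean of per-site
  values) is not stated in the source analyses; the weighted tool default is
  used, with the alternative one line away in the code.
* No ancestral-allele polarization, no coalescent back-end, no
  selection-coefficient inference, no read-level processing: inputs begin at
  genotypes.
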