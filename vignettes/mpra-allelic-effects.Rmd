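---
title: "Allelic and condition-specific regulatory effects from MPRA counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic and condition-specific regulatory effects from MPRA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpragxe)
```

## The assay and its statistical structure

A biallelic targeted STARR-seq library tests tens of thousands of candidate
regulatory SNPs at once. Each *target* is a ~200-nt designed sequence with
the SNP at its center; it is synthesized as two allelic *constructs*, each of
which can integrate into the reporter plasmid in the forward or reverse
orientation. The plasmid pool (the *DNA library*) is transfected into cells,
self-transcribed reporter RNA is sequenced, and reads are assigned to
(SNP, direction, allele). The unit of testing is the *SNP/direction pair*:
regulatory elements can act in an orientation-dependent way, so the two
orientations are analyzed separately and never pooled.

Three questions, three models:

1. **Differential activity** — does treatment (here: caffeine vs water
   control) change a target's overall reporter output? A count GLM per
   target.
2. **Allele-specific expression (ASE)** — within a condition, do the two
   alleles produce different RNA amounts relative to their DNA pool
   proportion? A beta-binomial model per replicate, meta-analyzed.
3. **Conditional ASE (cASE)** — does the allelic effect differ between
   conditions? This is the molecular signature of a genotype-environment
   interaction, tested by contrasting the two conditions' z-scores.

The pipeline's entry point is the long-form allele count table
(`read_allele_counts()`); upstream read processing (demultiplexing,
alignment, UMI deduplication, pileup) is external, with one exception: the
UMI pattern rule is kept as a stand-alone validator (`validate_umi()`,
default pattern `RDHBVDHBVD`) because it is a pure string contract that is
cheap to verify.

## ASE: beta-binomial effects anchored on the DNA pool

For one replicate of one SNP/direction pair, let $k$ of $n$ RNA reads carry
the reference allele. We model $k \sim \mathrm{BetaBin}(n, \mu, \rho)$ with
$\mathrm{Var}(k) = n\mu(1-\mu)\,(1 + (n-1)\rho)$, and estimate the log-odds
$\beta = \mathrm{logit}(\mu)$ by maximum likelihood after adding a
Haldane–Anscombe pseudocount of 0.5 to both allele counts (monoallelic
observations stay finite). The overdispersion $\rho$ is estimated **once per
condition** by pooling all pairs with the mean fixed at each pair's DNA
proportion (`estimate_dispersion()`), then held fixed for every fit; no
other information is shared across SNPs.

The null expectation for the RNA reference fraction is not 1/2 but the
pool's composition: the DNA proportion $p_0$, estimated from the summed DNA
counts with the same pseudocount (`estimate_dna_proportion()`). Replicates
are combined by inverse-variance weighting,
$\hat\beta = \sum_i w_i \beta_i / \sum_i w_i$ with $w_i = 1/se_i^2$ and
$se_{meta} = (\sum_i w_i)^{-1/2}$, and the test statistic is

$$z = \frac{\hat\beta - \mathrm{logit}(p_0)}{se_{meta}}.$$

The subtraction is on the log-odds scale: $\hat\beta$ is a log-odds, so
subtracting a raw proportion would be dimensionally inconsistent. Pairs with
fewer than 4 usable replicates (nonzero RNA depth) per condition, or with
fewer than `min_dna_reads` (default 100) DNA reads, are reported untested.
BH correction is applied within condition across all tested SNP/direction
pairs — both orientations in one family — and significant ASE is FDR < 10%.

### Why the standard errors are anchored at the null

Two properties of the per-replicate MLE required care; both were found by
simulation against the generator's ground truth, and both would silently
miscalibrate the downstream GxE test if ignored.

First, *curvature standard errors at each replicate's own optimum make the
weights data-dependent*: the log-odds information $n\hat\mu(1-\hat\mu)$-like
term is largest when $\hat\mu$ drifts toward 1/2, so inverse-variance
weighting systematically upweights replicates that drifted toward the DNA
proportion's null, biasing the weighted mean and deflating the
between-condition contrast (genomic-control $\lambda \approx 0.82$ under a
pure null). `run_ase()` therefore uses *score-type* standard errors
evaluated at the common null $p_0$, keeping the weights independent of the
estimates. (`fit_replicate()` still reports the classical curvature standard
error for a single fit, which is what its oracle tests check.)

Second, with fixed $\rho$ the *effective* information per replicate
saturates at $1/\rho$ no matter how deep the sequencing, so the logit
nonlinearity never becomes negligible and no first-order variance formula is
exact at any depth. Instead of an approximation, the exact null moments of
the pseudocounted MLE are enumerated: for a grid of $(n, p_0)$ the estimator
$\hat\beta(k)$ is evaluated for every $k = 0..n$ and its mean and sd taken
under the beta-binomial pmf, then interpolated (the sd is stored relative to
a smooth first-order formula, so interpolation error is ~$10^{-3}$). Each
replicate's effect is centered by the exact null mean and weighted by the
exact null sd. Under the generator's null at 20,000 pairs and mean depth
300 this yields $|\mathrm{sd}(z) - 1| \lesssim 0.04$ and genomic-control
$\lambda$ within a few percent of 1; the tests assert these bounds.

One deliberate simplification remains: sampling noise of the DNA proportion
is *not* propagated into $se_{meta}$. It inflates the per-condition z
variance by a few percent (the shared DNA error cancels in the
between-condition contrast), which is why deep DNA sequencing — and the
`min_dna_reads` filter — matter. Estimating $\rho$ against the *estimated*
DNA proportion would absorb exactly this noise into the dispersion; the
measurement-error correction in `estimate_dispersion()` (subtracting the
mean $1/(N_{dna}+1)$ contribution) removes it.

## cASE: the squared z-difference with genomic control

With per-condition z-scores $Z_T$ (treatment) and $Z_C$ (control), the
conditional-ASE statistic is

$$(\Delta Z)^2 = \frac{(Z_T - Z_C)^2}{2},$$

which is $\chi^2_1$ under the null of equal allelic effects in both
conditions. Only pairs tested in *both* conditions are eligible. The
ensemble is calibrated by genomic control: $\lambda_{GC} =
\mathrm{median}((\Delta Z)^2) / m_1$ with $m_1$ the $\chi^2_1$ median
(~0.4549, computed from the inverse CDF at run time), and p-values are the
upper $\chi^2_1$ tail of the statistic divided by $\lambda_{GC}$. The
median-ratio estimator is used without flooring at 1 — deflation is allowed
and reported, since an ensemble dominated by true effects legitimately
inflates the median and over-correction is then conservative. The verbal
notion of cASE ("significant in only one condition, or significantly
different between conditions") is operationalized *only* by this statistic;
no extra one-condition rule is layered on. Calls are BH FDR < 5%, with a
relaxed nominal p < 0.0215 follow-up set whose threshold is a plain
configurable cutoff.

## Differential activity: a per-target NB Wald GLM

Counts for a target's two allelic constructs across all RNA samples of one
direction follow

$$\log \mathbb{E}[y] = \log s + \beta_0 + \beta_{allele}\,I[\mathrm{alt}] +
\beta_{trt}\,I[\mathrm{caffeine}]$$

with median-of-ratios size factors $s$ (`size_factors()`). The allele term
is in the model because PCA of the sample-by-allele matrix shows the allele
axis dominating the variance in this assay (`pca_qc()`). This stage is a
deliberately self-contained negative-binomial Wald GLM — per-target
dispersion, no shrinkage across targets, no independent filtering, no
fold-change moderation — so its computation is fully specified here rather
than delegated.

Two finite-sample choices keep the test calibrated at 24 observations per
target (2 alleles x 12 samples): the dispersion is profiled by **Cox–Reid
adjusted** likelihood (the adjustment $-\tfrac12 \log\det X'WX$ removes the
$O(p/n)$ downward bias of plain ML; it is a bias correction, not shrinkage),
and the Wald statistic $\beta_{trt}/se$ is referred to a **t distribution
with residual degrees of freedom** ($n - p = 21$) rather than a normal —
with per-target dispersion estimation the normal reference is liberal
(measured type-I ~0.097 plain, ~0.05 with both corrections; the tests assert
[0.03, 0.07] and p-value uniformity under the null). A likelihood-ratio
variant (`test = "lr"`) is exposed for cross-checks. Targets are called
significant at BH FDR < 10% *in either direction* (directions are separate
BH families), with the direction of change taken from the significant
direction's fold change (ties: smaller q).

## Motif and annotation enrichment

PFMs (JASPAR text, `read_jaspar_pfm()`) become log-odds PWMs in bits with a
0.25 per-cell pseudocount against a uniform background (`pfm_to_pwm()`);
both defaults follow common scanner practice. Scanning reports every window
scoring at least 10 bits, on both strands by default (the library carries
both orientations; strand can be switched off), with N-containing windows
skipped. Motif occurrence is counted once per target, and motifs present in
fewer than 100 targets are dropped — the boundary reading keeps occurrence
exactly 100 (`strict = TRUE` gives the > 100 reading).

Per-motif enrichment is a one-sample test of proportions with Yates
continuity correction: observed $n_c/n_d$ (significant targets within this
motif over targets within this motif) against the any-motif baseline
$n_a/n_b$, with a Wilson continuity-corrected 95% CI. Significance is
reported at p < 0.05 without cross-motif correction (a BH option exists but
is off by default, matching how such scans are conventionally reported).
Annotation enrichments (open chromatin, eQTL membership) cross-tabulate
significance by annotation and use Fisher's exact test, reporting the
conditional-MLE odds ratio and the fold enrichment (annotated fraction among
significant over annotated fraction among non-significant). Interval
membership is 0-based half-open everywhere (a variant at `pos` is inside
`[start, end)`), and chromosome names match literally.

## The synthetic data generator

`sim_config()` defaults emulate the assayed study: 43,556 targets of 200 nt
with a centered SNP, 1676/43556 negative controls, 6 replicates per
condition, mean depth ~450 reads per SNP/direction per replicate (the real
libraries averaged ~39M reads over ~87k constructs). Structure and
rationale:

* **Depth** per SNP/direction/replicate is negative-binomial with
  dispersion 0.5 — a heavy-tailed depth stresses the >= 4-replicate filter
  the way uneven library representation does in practice.
* **DNA pool proportions** are Beta(5, 5): uneven but rarely extreme input
  representation. The pool is sequenced at `dna_depth_factor = 10` times the
  RNA replicate depth with *binomial* noise (`rho_dna = 0`): $p_0$ is
  defined as the pool composition, so overdispersion is a property of RNA
  relative to the pool, and the DNA input is a single deeply sequenced
  library. Because the analysis deliberately does not propagate DNA noise,
  a shallow DNA pool would be a generator artifact rather than a realistic
  condition.
* **RNA counts** are beta-binomial around
  $\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \beta_{condition})$ with
  $\rho = 0.05$, a typical MPRA overdispersion scale.
* **True effects**: a fraction `frac_ase` (default 5%) of SNPs get one
  shared log-odds effect in both conditions; a disjoint `frac_case`
  (default 1%) get independent per-condition effects — the simplest
  structure making $Z_T \neq Z_C$ detectable. Effects are Normal(0,
  `effect_sd`); the true effect-size distribution and fractions are
  conventions, not measured quantities. Negative controls have all effects
  exactly zero. Reverse-orientation counts share the forward effects by
  default (`direction_specific_effects` switches to independent draws).
* **Activity counts** are negative-binomial with per-target lognormal
  baselines, lognormal size factors, an allele fold-change (the dominant
  PCA axis) and a treatment fold-change for `da_frac` of targets.
* **Motif planting** substitutes a PFM's consensus at a random offset that
  never covers the central SNP, at rate `motif_plant_rate`, multiplied by
  `motif_ase_multiplier` in targets carrying a true allelic effect — this
  induces the enrichment signal the proportion test should recover.

Identical configs (including seed) give byte-identical outputs; the truth
tables carry every flag and effect for recovery tests.

**What passing tests do and do not show.** The generator matches the
*statistical* structure the models assume: beta-binomial allelic counts
around an uneven pool, NB activity with multiplicative treatment effects,
independent targets. Real data add what it omits — mapping bias toward the
reference allele, linkage between nearby SNPs, construct-specific secondary
structure, DNA pool overdispersion across replicates, batch structure beyond
scalar size factors. Calibration and FDR results here certify the
implementation, not robustness to those artifacts.

## Numerical choices and degenerate inputs

* Beta-binomial fitting is a safeguarded Newton iteration on the log-odds in
  [-10, 10] (digamma/trigamma derivatives), with a per-fit `optimize()`
  fallback; it matches a grid-search oracle to $10^{-3}$ over 200 random
  count pairs in the tests.
* Zero-total-read replicates are flagged missing and excluded from
  meta-analysis; zero DNA counts are handled by the pseudocount; all-zero
  conditions make a DA target untested with a logged reason; a constant
  activity matrix makes `pca_qc()` fail loudly rather than return NaNs.
* The exact-moment calibration grid spans depths 1..max and DNA proportions
  0.02–0.98 (21 logit-spaced points); values outside are clamped.
* The $\chi^2_1$ median and all quantiles come from `qchisq()` at run time,
  never hard-coded.
* Problem sizes in the tests — 20,000 pairs for null calibration, 6,000
  targets for FDR, 200 oracle fits, 20 replicate libraries for motif power —
  were chosen as the smallest sizes at which the asserted tolerances are
  comfortably above Monte-Carlo noise.

## Known limitations

* DNA-proportion noise is not propagated into the ASE standard error
  (handled instead by deep-DNA QC); with a shallow DNA pool the z-scores
  would be anticonservative.
* $\rho$ pooled per condition with means fixed at the DNA proportions
  absorbs true allelic effects when many are present, inflating $\rho$ and
  making both ASE and cASE conservative in effect-rich libraries.
* The cASE test compares exactly two conditions; no multi-condition
  generalization is attempted.
* Per-target NB dispersion without sharing is honest but less powerful than
  moderated approaches at this replicate count; the calibration choices (CR
  adjustment, t reference) trade a little power for type-I control.
* The motif scanner is exhaustive and exact but makes no attempt at motif
  redundancy reduction or information-content trimming.
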