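---
title: "Methods: smooth-pursuit phenotyping and quantitative-trait association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smooth-pursuit phenotyping and quantitative-trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitgwas)
```

# Overview

`pursuitgwas` implements a complete oculomotor genome-wide association
workflow: 1 kHz horizontal eye-position traces are reduced to four
session-level phenotypes (RMSE of eye relative to target, pursuit gain,
catch-up saccade rate, anticipatory saccade rate), and a quantitative
phenotype is tested for additive association against a genotype matrix with
sex and genotype-PC covariates, within-cluster max-T permutation
correction, LD-based clumping, and noncentral-F power analysis.  Because no
real recordings or genotypes ship with the package, a first-class
synthetic-data module generates every input with a ground-truth log, and
the test suite scores each stage against that truth.

# The oculomotor task and its phenotypes

The pursuit target starts at a central fixation point for a uniformly drawn
500–1500 ms, then moves horizontally at a constant speed (10, 20 or
30 deg/s), reversing at ±15 deg so that its position traces a triangular
waveform for 5.5 cycles; a session has eight trials per speed.  Calibration
segments — 1000 ms fixations at 15, 10, 5, 0, −5, −10, −15 deg — are
interleaved at regular intervals (every 6 trials by default).  The recorded
signal is an affine distortion of true eye position plus sensor noise
(default SD 0.1 deg, i.e. about six arcmin).

Processing follows the chain calibration → blink rejection →
differentiation → saccade detection/classification → phenotypes:

* **Calibration** regresses the mean signal at each fixation target on the
  target values (OLS); calibrated position is `(signal − offset)/gain`,
  applied to all data until the next calibration.  Degenerate fits
  (fewer than two distinct targets, |gain| below 1e−6) are errors.
* **Blink rejection** marks samples that are off the position scale
  (|position| > 25 deg) or move impossibly fast (|velocity| > 1000 deg/s),
  padded by 50 ms on each side.  Trials with less than 50% valid samples
  are dropped.
* **Differentiation.** Velocity and acceleration come from cascaded
  second-order Savitzky–Golay derivative filters with 21 ms windows.
  Double-differencing raw 1 kHz data at a 6-arcmin noise floor is
  unusable: the cascade keeps the acceleration noise SD near
  400–500 deg/s² so that the detection threshold sits well below the
  acceleration of a 2 deg saccade.  A single 21 ms window followed by raw
  first differences leaves the threshold above small-saccade
  accelerations, which is why the second derivative is also taken with a
  polynomial filter.
* **Saccade detection** uses the participant-relative threshold: six times
  the median across trials of the SD of the acceleration signal in each
  trial's first 80 ms (steady fixation, so this measures the noise
  floor).  The first 21 ms of each trial — the derivative filter's
  one-sided startup transient, whose noise amplification is much larger
  and erratic — are excluded from that window, which stabilizes the
  threshold to a few percent across sessions.  Candidate runs above
  threshold are merged across gaps below 20 ms, extended to the
  20%-of-threshold re-crossings, discarded when shorter than 10 ms or
  touching invalid samples.  Saccade amplitude is the position change
  over the event minus the smooth-pursuit drift expected during it
  (baseline velocity taken as the median eye velocity in windows 25–60 ms
  on either side); without this correction a 40 ms event during 20 deg/s
  pursuit would inflate every amplitude by almost a degree and could even
  flip the apparent direction of small backward saccades.
* **Classification** compares the absolute eye–target error 5 ms before
  onset and 5 ms after offset (probes are offset to avoid transient
  overshoot): error-decreasing saccades along the target-motion direction
  are catch-ups; error-increasing ones along the motion with amplitude
  above 1.5 deg are anticipatory; everything else is `other`.
* **RMSE** uses the complete valid pursuit signal including saccades,
  excluding blink-masked samples.  **Gain** is the mean ratio of eye to
  target velocity over valid, non-saccadic samples with target
  eccentricity ≤ 10 deg (this excludes direction-reversal regions; the
  reversal exclusion applies to gain only, not to RMSE).  Session values
  are unweighted means of per-trial values across all speeds (a
  pooled-sample RMS alternative is available via `aggregate = "pooled"`);
  saccade rates are total class counts divided by total valid tracking
  time.  Whether per-speed averaging should precede the across-speed mean
  is not determined by the protocol; the unweighted mean over trials was
  chosen and exposed as the default.

# What the trace simulator emulates — and what it does not

The simulated smooth eye trace is the target delayed by the pursuit
latency (default 100 ms, a typical human value) and attenuated by the
pursuit gain, with direction reversals rounded by a 120 ms moving average
(real pursuit anticipates reversals rather than turning on a corner; the
rounding also keeps the reversal from masquerading as a saccade).  Saccades
are injected as minimum-jerk position steps of 30–80 ms, duration growing
with amplitude: catch-ups cancel the accumulated eye–target error and are
injected only when the eye genuinely lags (error ≥ 0.5 deg in the motion
direction), anticipatory saccades land ahead of the target by
`anticipatory_amp_deg` plus the current error magnitude and are injected
only while tracking is tight (error ≤ 2 deg), which keeps the eye's lead
bounded and makes every injected event satisfy its own class definition at
injection time.  An event whose placement fails (refractory overlap,
reversal zone, blink, class condition) is redrawn at a later time rather
than dropped, so injected counts stay Poisson at the configured rates.
Blinks clamp the signal to an off-scale constant with 50 ms tapered edges.

Not emulated: vertical/torsional components, head movement, smooth
variations of gain within a trial, pupil artifacts, corrective dynamics
after saccadic overshoot, and instrument drift between calibrations.
Passing tests therefore demonstrate that the analysis chain recovers known
parameters from data obeying this generative model — not that it is robust
to every artifact of real infrared oculography.

# The cohort simulator

Genotypes are drawn under Hardy–Weinberg equilibrium at independent SNPs
with ancestral minor-allele frequencies uniform on a configurable range
(default [0.05, 0.5]).  Population structure, when requested, disperses
cluster allele frequencies around the ancestral value with a
Balding–Nichols beta draw at an Fst-like divergence parameter.  The
phenotype sits on a standardized scale,

$$y = \beta\,(g - 2p) + s\,\frac{\text{sex}-\tfrac12}{\tfrac12} + e,$$

with the residual variance chosen so that the total variance is exactly 1;
the causal SNP then explains $\beta^2\,2p(1-p)$ of the phenotype variance.
Defaults are the study's operating point: $n = 980$, causal MAF 0.49,
per-allele effect $\beta = 0.29$ SD (variance share ≈ 0.042), and a sex
component of 0.2 SD — a moderate value consistent with the reported
sex differences, since the protocol does not pin the sex effect on the
standardized scale.  The causal SNP keeps its ancestral frequency in every
cluster so its effect size is exactly the configured one.  One simulated
phenotype per participant plays the role of the session-level RMSE on a
standardized scale; the association stages consume standardized phenotypes
throughout, matching the SD-unit effect sizes they report.

A separate generator, `simulate_ld_block()`, embeds a 10-SNP
linkage-disequilibrium block (Gaussian-copula haplotypes with AR(1) latent
correlation) around a causal SNP inside a null genome, for exercising
clumping against a known causal position.  Its default effect size
(0.55 SD per allele at n = 400, variance share ≈ 0.13) gives the
index-SNP stage better than 99% analytic power at the 1e−5 index
threshold, so the clumping properties measure the clumping logic rather
than single-SNP detection power.

# Association methodology

* **QC order**: samples with call rate < 0.97 first, then SNPs with
  missingness > 2%, then SNPs with MAF < 1% (MAF computed after the sample
  exclusions — the alternative order is not determined by the protocol).
  Codes are re-oriented so allele 1 is minor.  Hardy–Weinberg exact
  p-values are computed for every survivor but are reported rather than
  filtered on by default, HWE deviation being conventionally inspected as
  post-association QC; a threshold flag exists.
* **HWE exact test**: full enumeration of heterozygote counts conditional
  on the allele counts, two-sided by summing configurations no more
  probable than the observed one; mid-p available but off by default.
* **Covariates**: sex (coded 0/1, female = 1) and the top three genotype
  principal components.  PCA centers each SNP at $2\hat p$ and scales by
  $\sqrt{2\hat p(1-\hat p)}$, mean-imputes missing codes for the
  decomposition only, and fixes signs by making the largest-magnitude SNP
  loading positive.
* **Per-SNP model**: OLS of phenotype on minor-allele count + covariates +
  intercept, per-SNP complete cases (the behavior of the standard GWAS
  tools; no imputation).  A vectorized Frisch–Waugh–Lovell path computes
  exact OLS statistics for all SNPs without missing genotypes at once.
  An optional rank transform replaces the phenotype by average ranks.
  P-values are floored at 1e−300 to keep −log10 finite.
* **Genomic control**: λ is the median observed 1-df chi-square over
  0.4549364, the standard median-based estimator (the protocol does not
  define its λ).
* **Max-T permutation**: phenotypes are shuffled only within
  identity-by-state clusters (complete-linkage tree on the pairwise IBS
  distance, cut at a configurable K).  Covariate rows travel with the
  phenotype, preserving the phenotype–covariate relationship the observed
  model conditions on; the regression is exactly refit per permutation
  (the projection identity makes this two small matrix products).  The
  corrected p-value uses the add-one estimator
  $(1 + \#\{\min p \le p_{obs}\})/(B+1)$, which can never be zero.
  Missing genotypes are mean-imputed per SNP inside this stage so observed
  and permuted statistics are computed identically.
* **Clumping**: greedy PLINK-style — smallest-p unclumped SNP below
  p1 = 1e−5 indexes a clump; unclumped SNPs below p2 = 0.01 within
  1250 kb and with genotype r² ≥ 0.1 join it; ties in p break by SNP id.
* **Power**: `power_ncf()` evaluates
  $1 - F_{\nu_1,\nu_2,\lambda}(F_{crit})$ with
  $\lambda = \tfrac{r^2}{1-r^2}\nu_2$ and $F_{crit}$ the $100(1-\alpha)$
  central-F percentile.  At $r^2 = 0.043$, $\nu_1 = 1$, $\nu_2 = 977$,
  $\alpha = 5\times10^{-7}$ the formula evaluates to 0.9402, confirmed
  against a Monte-Carlo oracle built from the definition of the
  noncentral F.
* **Sex-difference test**: the absolute difference of group-specific
  additive betas at one SNP, referenced to random re-splits of the cohort
  into the observed group sizes, add-one p-value; degenerate splits
  (within-group monomorphism) are redrawn and counted.

# Numerical and design choices

Open choices were resolved once and exposed as parameters: left/right
start directions alternate (4/4 per speed); calibrations recur every 6
trials; saccade onset/offset are the 20%-of-threshold re-crossings with
20 ms refractory merging and 10 ms minimum duration; positional error for
classification is probed at onset − 5 ms and offset + 5 ms; the IBS tree is
cut at a fixed K (the data-driven stopping rule behind the published
11-cluster grouping is not described); permutation covariates are re-fit
per permutation rather than residualized once (both are defensible; the
exact refit is the default because it is just as cheap here); the rank
transform applies to the phenotype only, not the genotype.  The
population-outlier and relatedness exclusions of a real cohort reduce, on
synthetic data, to the sample call-rate filter; PC-outlier and IBS-based
duplicate screens can be reproduced with `genotype_pca()` and
`ibs_distance()` directly.

Problem sizes in the shipped tests were chosen to exercise each claim at
the study's stated operating point while keeping a full run of the suite
in the minutes range: the null-inflation check uses one 980 × 5000 cohort;
effect-size recovery uses 200 cohorts of 980 × 200; max-T calibration uses
200 replicates of a 500 × 200 cohort with 500 permutations; the oculomotor
oracle suite scores 20 full sessions; the HWE implementation is compared
with an independent enumeration oracle at every genotype-count triple up
to n = 200.

# Known limitations

* The trace simulator's saccade/blink morphology is idealized; detector
  performance on real infrared oculography will be lower than on the
  generative model.
* `ld_r2()` is composite genotype LD; no haplotype phasing.
* The pipeline is single-phenotype, autosomal, linear-model only: no
  imputation, dosages, mixed models, or binary traits.
* With `reversal_smooth_ms = 0` the simulated eye turns on a corner and
  the acceleration detector will flag reversals; the default rounding
  (120 ms) reflects real pursuit and avoids this.
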