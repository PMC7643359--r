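---
title: "Multiscale EEG complexity and fluid intelligence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale EEG complexity and fluid intelligence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state EEG is irregular at many timescales at once, and the degree of
that irregularity — its *complexity* — differs reliably between people.
`neurocx` implements a complete pipeline for asking whether that complexity
carries information about fluid intelligence (*gf*): it computes multivariate
multiscale sample entropy (mMSE) profiles of multichannel recordings over
named scalp channel sets, reduces each profile to a small set of scalar
features, extracts a single *gf* factor from a battery of six reasoning
tests, and relates features to *gf* with partial least squares regression
(PLSR) and bootstrap-based predictor relevance.

Every stage is also exercised against seeded synthetic data with known
ground truth, so the pipeline's statistical behavior (calibration, power,
sign recovery) is testable without any recorded data.

# Multivariate multiscale sample entropy

## Sample entropy

For a univariate series, sample entropy asks: given that two short templates
of m consecutive points agree within a tolerance r (Chebyshev distance,
self-matches excluded), how often do they still agree when extended by one
point? Writing B^m and B^{m+1} for the fractions of matching template pairs
of lengths m and m+1,

    SampEn = -ln( B^{m+1} / B^m ).

Low values mean the signal is predictable (a match tends to stay a match);
high values mean irregularity.

## Composite delay vectors

For p simultaneous channels the templates become *composite delay vectors*:
channel k contributes m_k points sampled every tau_k steps, and the pieces
are concatenated into one vector of length m = sum(m_k). With
n = max(M) * max(tau), a p-channel record of length N yields N - n such
vectors. Matching uses the same Chebyshev distance and tolerance r.

Extending a composite vector admits two conventions, and the package
implements both:

* **per_channel** (default): the embedding dimension of one channel at a
  time grows from m_k to m_k + 1; pooling over channels yields p(N - n)
  extended vectors of length m + 1. This is the convention of the reference
  multivariate sample-entropy implementation. The extra sample sits inside
  the grown channel's block; the layout matters, because with cross-channel
  pooling an append-at-end layout would make pairs sharing a base vector
  spuriously close.
* **simultaneous**: every channel gains its next sample at once, giving
  N - n vectors of length m + p.

The two coincide at p = 1; for p > 1 they answer slightly different
conditional-probability questions, and published descriptions of the method
are not always explicit about which is meant, which is why the choice is a
visible parameter rather than a constant.

## Coarse-graining and the profile

Scale ε replaces the series by averages over non-overlapping windows of ε
samples (length floor(N/ε)); the entropy is recomputed at each ε = 1..12.
Channels are normalized to zero mean and unit variance **once, at scale 1**;
the coarse-grained series are *not* re-standardized and r stays an absolute
0.15 (the classic multiscale-entropy convention). Because averaging shrinks
the variance of temporally white noise but barely touches 1/f noise, this
convention is what makes white-noise profiles fall with ε while 1/f profiles
stay flat — the qualitative signature the profile features quantify.

Defaults follow standard practice for resting EEG: m_k = 2, tau_k = 1,
r = 0.15, ε = 1..12, and 4-channel sets, with 10,240-sample (40 s at 256 Hz)
epochs and a final |amplitude| > 111 µV epoch rejection. A warning is issued
when the coarsest series falls below the p·10^m sample-count guideline.

## Numerical notes

Match counting sorts vectors by their first coordinate and scans a sliding
window with early exit — exact and memory-bounded; a blocked vectorized R
engine (configurable block size) gives bit-identical counts, and both are
tested against a naive double loop. Undefined entropies (zero match counts)
propagate as flagged `NaN` rather than ±Inf; per-subject profiles average
per-epoch profiles scale-wise, skipping flagged entries and recording how
many epochs contributed. Ties at exactly r count as matches.

**Estimator regime.** With r = 0.15 the match probability per added
coordinate for *independent* unit-variance Gaussian channels is about
0.084, so an 8-dimensional template (p = 4, m_k = 2) matches with
probability ~0.084^8 ≈ 2·10⁻⁹ — essentially never in a 10,240-sample
epoch. The estimator is therefore only defined at p = 4 when channels share
structure, as neighboring scalp electrodes do through volume conduction.
This drives a central design choice of the synthetic generator (below) and
is worth remembering when applying the method to decorrelated (e.g.,
spatially whitened) data.

# Profile features

Each (subject, channel set) profile is reduced to three scalars:

* **AUC** — trapezoidal area under the 12-point profile over the scale
  index (unit spacing): total complexity.
* **MaxSlope** — the signed maximum of (v_j - v_i)/(j - i) over scale pairs
  1 ≤ i < j ≤ 4: the steepest fine-scale rise.
* **AvgEnt** — the mean of scales 9-12: the coarse-scale complexity level.

With nine channel sets (F, FL, FR, C, P, PL, PR, ML, MR — four electrodes
each) this gives 27 features, plus 18 between-set differences
(first-named minus second-named) for the pairs F-P, FL-PL, FR-PR, FL-FR,
PL-PR and ML-MR: 45 predictors per subject. Column names are fixed
(`AUC_F`, `AvgEnt_FL-FR`, ...) so external tables can be mapped in with a
rename dictionary.

# The gf factor

Six reasoning-test scores (RAPM, CFT3, Paper, Analogies, Number, Pattern)
are reduced to one factor: the first principal component of their
correlation matrix. The component's eigenvalue (out of 6) is the variance
explained; factor scores are standardized to mean 0, SD 1. This
eigenvalue-based convention is the one the explained-variance arithmetic of
typical batteries identifies (an eigenvalue of 3.7 on 6 tests is 61.8% of
the variance); more elaborate factor estimators differ negligibly for a
battery this collinear.

# PLSR with relevance bootstrap

The 45 predictors are centered and standardized; PLS1 components are
extracted by orthogonal-scores NIPALS (equivalent, for a univariate
response, to SVD deflation of the cross-product X'y in order of decreasing
covariance). With all components the fit equals least squares; with one
predictor it equals simple regression — both limits are asserted
numerically in the tests, and fitted values are cross-checked against an
independent PLS implementation.

## Choosing the number of components

A cross-validated error curve (leave-one-out by default; k-fold available)
is computed for 0..K components, where the 0-component model predicts the
training-fold mean. Two selectors are provided:

* **first local minimum** of the curve (the last point qualifies when the
  curve is still decreasing there);
* **randomization test** (van der Voet): paired sign-flip test on
  per-observation squared prediction errors against the curve's global
  minimum; the smallest count not significantly worse at α = .05 is chosen
  (10,000 permutations by default).

Under null data the curve is typically minimized at 0 components and the
randomization selector returns 0 in at least 95% of replicates — it is
conservative, which is the desirable direction for a gatekeeper.

## Bootstrap relevance

With the component count fixed, subjects are resampled with replacement
(B = 10,000 by default), standardization and fit are repeated per
replicate, and each coefficient gets a bootstrap interval; predictors whose
interval excludes zero are flagged relevant, reported sorted into positive
and negative blocks by magnitude.

Two interval types are available, and the choice matters more than usual:

* **percentile** (default): plain bootstrap quantiles. On null cohorts
  (n = 119, 45 independent predictors, one component) the flag rate is
  ~5%, i.e. nominal.
* **bc**: Efron's median bias correction, the flavor named in several PLS
  packages. For PLS1 coefficients it is strongly anti-conservative (flag
  rates near 30% under the same null): resampling inflates ‖X'y*‖, which
  multiplicatively shrinks replicate coefficients; the correction misreads
  that shrinkage as estimation bias and pushes both interval ends away
  from zero. It is provided for comparability, not as the default.

No automatic outlier removal is performed anywhere; a subject exclusion
list is accepted instead, and component counts can be forced per group,
so published analyses that made such choices can be replayed exactly.

# The synthetic cohort generator

Three generation paths, all seeded and deterministic:

* **Signals.** Each channel mixes unit-variance 1/f noise (FFT spectral
  shaping, DC bin zeroed), white noise and an optional 10 Hz oscillation:
  `pink_weight·pink + (1-pink_weight)·white + alpha_amp·sin(2π·10·t+φ)`,
  scaled to microvolts. Channels share a common source per noise type with
  weight `spatial_cor` (inter-channel correlation). The default
  `spatial_cor = 0.98` was calibrated once so that 4-channel sets sit in
  the regime where the entropy estimator is well defined and white/pink
  mixtures reproduce the canonical profile shapes; fully independent
  channels (`spatial_cor = 0`) put p = 4 estimation out of reach of any
  realistic epoch length (see the estimator-regime note above).
* **Feature tables.** Rows from a zero-mean multivariate normal over the 45
  named predictors (any PSD covariance), with
  gf = features·β + N(0, σ²) for a user-chosen sparse β — ground truth for
  calibration and power studies. Sex alternates M/W and has no generative
  effect unless the user builds one in, so sex-stratified analyses can be
  tested under both null and constructed differences.
* **Test batteries.** score_j = λ_j·gf + sqrt(1-λ_j²)·noise, affinely
  mapped to realistic test means and SDs. The default loadings are scaled
  so the implied correlation matrix has first eigenvalue 3.706 — a first
  factor explaining 61.8% of battery variance, typical of fluid-intelligence
  test sets. (Note that with the single-factor model the first eigenvalue is
  1 + 5λ² for equal loadings λ, *not* 6λ²: equal loadings of 0.786 give a
  68.1%-variance factor, a point the tests pin down with an
  eigen-decomposition oracle.)

The **end-to-end cohort** ties gf linearly to each subject's pink weight so
higher-gf subjects have flatter coarse-scale profiles; the packaged study
conditions are 20 subjects, pink weight spaced over [0, 0.7],
`spatial_cor = 0.995`, and three 2,048-sample epochs per subject. The
shorter epochs keep the run fast, and the raised correlation plus epoch
averaging keep the coarse-scale estimator in its unbiased regime — at 2,048
samples with the default settings the sparse-match downward bias grows with
pink weight and can invert the observed complexity-gf association, which is
itself a useful cautionary result about short epochs.

What the generator does **not** emulate: volume-conducted topographies from
dipole sources, artifacts, nonstationary state changes, or any realistic
spatial covariance beyond the single shared-source parameter. Passing tests
therefore demonstrate the pipeline's statistical machinery, not the
biological claim; recorded data remain the only arbiter of that.

# Pipeline

`run_pipeline()` executes simulate (or read) → epoch extraction → profiles
→ features → gf factor → group PLSR from one configuration list (or
YAML/JSON file), writing every intermediate artifact as CSV, a resolved
configuration snapshot, a stage log with counts (epochs kept/dropped,
subjects excluded for undefined features, bootstrap redraws) and md5
checksums of the data artifacts; identical configurations reproduce
identical checksums. `validate_config()` reports errors (unknown channel
sets, missing inputs, unusable epoch geometry) and warnings (the p·10^m
guideline) without computing anything. A master seed derives per-stage
seeds, so bootstrap and permutation stages are reproducible end to end.

Subjects whose profile features are undefined at some scale are excluded
from the feature table with a log entry rather than aborting the run; the
group analysis then proceeds with the remainder (minimum group size 10).

# Worked example

```{r, eval = FALSE}
library(neurocx)

tab <- generate_feature_table(cohort_spec(
  n_subjects = 119, true_beta = c(`AvgEnt_FL-FR` = 0.6), seed = 7))
fit <- complexity_plsr(gf ~ ., tab, group = "all", ncomp = "auto",
                       n_boot = 1000, n_perm = 1000, seed = 1)
print(fit)
summary(fit)
plot(fit)
```

# Known limitations

* The entropy estimator is undefined when no template matches exist;
  the package flags rather than extrapolates, and short epochs at coarse
  scales are biased downward even when defined. Epoch lengths below ~10^4
  samples deserve suspicion at ε near 12.
* PLS1 only (univariate response); multi-response PLS2 is out of scope.
* The randomization selector is conservative under the null (it selects 0
  components essentially always, not 95% of the time); its level is an
  upper bound, not an equality.
* EDF support covers continuous 16-bit recordings with a common sampling
  rate; EDF+ annotations and variable-rate signals are not parsed.
* Refined/composite multiscale variants (moving-average coarse-graining,
  RCMSE), frequency-resolved entropy and surrogate testing are not
  implemented.
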