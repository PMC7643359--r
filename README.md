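# neurocx

Spatiotemporal complexity of multichannel resting-state EEG and its
relation to fluid intelligence.

`neurocx` is an R package for researchers who want to quantify how
irregular a multichannel neural time series is across temporal scales and
scalp regions, and to relate that complexity to a behavioral trait. It
implements, end to end:

* **Multivariate multiscale sample entropy (mMSE).** For p simultaneous
  channels, composite delay vectors concatenate m_k delay-embedded samples
  per channel (lags tau_k); with B^m and B^{m+1} the fractions of vector
  pairs within Chebyshev distance r at lengths m and m+1,

      mMSE(M, tau, r, eps) = -ln( B^{m+1} / B^m ),

  computed after coarse-graining each channel at scale eps (non-overlapping
  eps-sample averages), for eps = 1..12. Defaults: m_k = 2, tau_k = 1,
  r = 0.15 on unit-variance channels, nine named 4-electrode channel sets
  (F, FL, FR, C, P, PL, PR, ML, MR), 10,240-sample epochs with
  |amplitude| > 111 µV rejection.
* **Profile features.** Per profile: trapezoidal area (*AUC*), signed
  maximum pairwise slope over scales 1-4 (*MaxSlope*), mean of scales 9-12
  (*AvgEnt*); plus between-set differences for six set pairs — 45
  predictors per subject.
* **A single gf factor** from six reasoning tests (first principal
  component of their correlation matrix, standardized scores).
* **PLS regression with relevance bootstrap.** PLS1 with cross-validated
  component selection (first local minimum of the CV curve, or van der
  Voet's randomization test), and bootstrap confidence intervals flagging
  predictors whose interval excludes zero; overall or sex-stratified.
* **Seeded synthetic cohorts** (signals with controllable 1/f content,
  feature tables with known sparse effects, single-factor test batteries)
  so every stage is testable with known ground truth.

## Worked example

```r
library(neurocx)

# a 119-subject synthetic cohort in which one difference feature drives gf
tab <- generate_feature_table(cohort_spec(
  n_subjects = 119, true_beta = c(`AvgEnt_FL-FR` = 0.6), seed = 7))

fit <- complexity_plsr(gf ~ ., tab, group = "all", ncomp = "auto",
                       n_boot = 1000, n_perm = 1000, seed = 1)
print(fit)
#> Complexity ~ gf PLS regression (all sample, n = 119)
#>   components: 1 used (local minimum: 1, randomization test: 0)
#>   response variance explained: 47% (total 47%)
#>   relevant predictors: 4 of 45
head(summary(fit)$relevance, 3)
#>       predictor coefficient ci_low ci_high    se relevant sign
#>    AvgEnt_FL-FR       0.505  0.275   0.483 0.055     TRUE    +
#>  MaxSlope_FR-PR       0.243  0.083   0.288 0.052     TRUE    +
#>    AvgEnt_FR-PR       0.161  0.014   0.224 0.054     TRUE    +
```

The fitted object answers the usual questions: `coef()` returns the
45 coefficients on the standardized predictor scale, `summary()` the full
relevance table (coefficient, bootstrap interval, SE, flag, sign; sorted
into positive and negative blocks), `plot()` the CV curve and interval
plot, `predict()` gf predictions for new feature rows. The constructed
driver `AvgEnt_FL-FR` is recovered as the top positive relevant predictor;
the two selectors disagree here because the van der Voet randomization
test is conservative (the leave-one-out improvement at one component has
p ≈ .075), while the first-local-minimum rule picks one component, which
is what the fit uses. Entropy profiles themselves come from
`mmse_profile()` / `subject_profile()`, features from
`assemble_features()`, and a full simulate → epochs → profiles → features
→ gf → PLSR run from `run_pipeline()`.

## Layout

* `R/`, `src/` — implementation (entropy engine match counting and the
  bootstrap inner loop are compiled).
* `tests/testthat/` — unit, property and acceptance tests; brute-force
  oracles live in `helper-oracles.R`.
* `vignettes/complexity-intelligence.Rmd` — the methods vignette: model,
  conventions, estimator regime, generator calibration, limitations.
* `scripts/acceptance.R` — see above.
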