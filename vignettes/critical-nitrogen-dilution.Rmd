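---
title: "Critical N dilution curves from leaf dry matter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical N dilution curves from leaf dry matter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndilute)
```

## The problem

A growing crop dilutes its nitrogen: as biomass accumulates, the minimum
plant N concentration that still permits maximal growth — the *critical* N
concentration — falls. Across many species this decline follows a power
law, here expressed on leaf dry matter (LDM, t ha⁻¹):

$$N_c\% = a \cdot \mathrm{LDM}^{-b},$$

with $a$ the critical concentration at LDM = 1 t ha⁻¹ and $b$ the dilution
exponent. Once a curve is in hand, the nitrogen nutrition index
$\mathrm{NNI} = N_a / N_c$ (measured over critical concentration) turns a
single sampling into a diagnosis: NNI near 1 is optimal, below 1 deficient,
above 1 luxury consumption. `ndilute` implements the full chain for
double-cropped rice — curve construction from multi-rate N trials,
between-group curve comparison, NNI, hold-out validation, and the
quadratic link from NNI to relative yield that locates the optimal
nutrition level.

## The Justes construction

Because the critical concentration is defined by a counterfactual
("the minimum N that still yields maximum growth"), it is estimated per
sampling date from the contrast between N-limited and non-limited
treatments:

1. **Classification.** A one-way ANOVA of LDM on N rate, followed by
   Tukey HSD comparisons against the treatment with the largest mean LDM,
   splits the rates into a *limited* group (significantly lower biomass)
   and a *non-limited* group. Published tables often carry only compact
   letter displays; `classify_letters()` applies the equivalent rule —
   share a letter with the top-biomass treatment and you are non-limited.
   A date is *usable* only with at least two limited and one non-limited
   treatment; other dates are discarded as uninformative.
2. **Oblique line.** OLS of PNC on LDM through the limited treatment
   means. Under N limitation both biomass and concentration rise with
   supply, so the line normally has positive slope; a non-positive slope
   is reported with a warning rather than silently dropped, since
   discarding such dates would bias the curve.
3. **Vertical line.** The date's maximum LDM is the mean LDM of the
   non-limited treatments.
4. **Critical point.** The intersection of the two lines:
   $N_c = \text{intercept} + \text{slope} \times \mathrm{LDM}_{max}$.

The points collected over dates (and, when pooling, varieties) are fitted
with the power law.

## Fitting and comparing curves

The default fit, `loglog_ols`, is OLS on the linearized form
$\ln N_c = \ln a - b \ln \mathrm{LDM}$ — the same scale on which the
between-group comparison is defined. `nonlinear_ls` refines that solution
by Levenberg–Marquardt least squares on the original scale, for users who
prefer residuals in concentration units. Either way $R^2$ is reported on
the original $N_c$ scale, `1 - SSres/SStot`, so the two methods are
directly comparable. No low-LDM plateau is imposed: the power law is
evaluated everywhere, with a warning outside the fitted LDM range instead
of a cap.

`compare_curves()` tests whether two point sets share one curve, on the
log–log scale: a sequential F-test of the slope-by-group interaction
(equal $b$), then — assuming a common slope — of the group main effect
(equal $\ln a$). The verdict is "different" when either test rejects.
Note the union of two $\alpha$-level tests has a familywise level near
$2\alpha$ by construction; the individual p-values are always reported so
users can apply their own convention.

```{r fixture-run}
bundle <- run_pipeline(load_table2_fixture(), quiet = TRUE)
bundle$curves[["early"]]
bundle$curves[["late"]]
```

## Diagnostics

* `compute_nni()` — NNI with a configurable optimal band. Exact equality
  with 1 is measure-zero on real data, so the default band is 0.95–1.05;
  `band = c(1, 1)` recovers the strict three-way rule.
* NNI needs a biomass at which to evaluate the curve. The package default
  is each observation's own LDM; `ldm_basis = "plateau"` instead uses the
  date's maximum LDM, a date-level alternative some workflows prefer. The
  choice matters most for severely limited treatments, whose own LDM sits
  far left of the plateau.
* `rmse()` / `n_rmse()` / `stability_class()` — hold-out validation error
  and its stability grade: n-RMSE below 10% excellent, 10–20% good,
  20–30% moderate, otherwise poor. The published inequalities leave the
  boundary values undefined; the half-open intervals `[0,10) [10,20)
  [20,30) [30,∞)` make the classes exhaustive and mutually exclusive.
* `validate_curve()` predicts critical N from hold-out maximum LDM and
  compares with the hold-out critical values — the direction of
  substitution used in practice (biomass is cheap to measure, N is not).
* `relative_yield()` scales treatment yields by the best yield of the
  same season-year; `fit_yield_response()` fits the quadratic
  $RY = c_0 + c_1 \mathrm{NNI} + c_2 \mathrm{NNI}^2$ and reports its
  vertex $(\mathrm{NNI}_{opt}, RY_{max})$, flagging upward-opening fits
  whose vertex is a minimum.

## The synthetic generator

`simulate_experiment()` exists so that every stage of the pipeline can be
tested against known truth. It generates exactly the structure the
analysis assumes:

* **Biomass.** Mean LDM at stage $s$ and rate $r$ is
  $\mathrm{LDM}_{pot}(s) \cdot r_{e\!f\!f}(r)$ with the Mitscherlich
  saturation $r_{e\!f\!f} = 1 - 2^{-(soil_n + r)/h}$. The exponential
  law of diminishing returns is the textbook N-response model in
  agronomy, and — unlike a Michaelis form — it can hold intermediate
  rates well below the plateau while the top rate clears it. `soil_n`
  (default 60 kg ha⁻¹) is the baseline soil supply that lets the zero-N
  control grow; the half-saturation scale $h$ (default 65 kg ha⁻¹) sets
  how fast the gap to the potential closes. The defaults reproduce the
  relative treatment spread visible in the packaged fixture's
  heading-stage LDM (roughly 0.47/0.76/0.89/0.95 of potential at
  0/75/150/225 kg ha⁻¹).
* **Limitation.** Treatments at ≥ 95% of potential biomass are
  non-limited; their mean PNC lies on the true curve times
  `luxury_margin` (default 1.05, a modest luxury uptake). Limited
  treatments lie strictly below the curve. By default their means fall on
  the date's true oblique line through the critical point
  (`limited_relation = "linear"`) — the geometry the construction assumes,
  which makes the generator's truth exactly recoverable in the noiseless
  limit; slope `sub_slope_factor * nc / ldm_max` with default factor 0.5,
  matching the positive within-date PNC–LDM association seen in the
  fixture. The `"proportional"` mode (PNC scaled by $r_{e\!f\!f}/0.95$)
  breaks that collinearity and serves as a robustness check.
* **Noise.** Multiplicative lognormal with mean exactly 1, independent on
  LDM and PNC, default CV 5% — the middle of the SE-to-mean ratios
  (~2–10%) in the packaged treatment-mean table. `noise_cv = 0` gives the
  exact means.
* **Yield.** One harvest per treatment, attached at `yield_stage`
  (default HS): relative yield is the configured quadratic at the
  treatment's true NNI (default vertex at NNI 1.04, RY 0.96), scaled by
  `max_yield` (default 7 t ha⁻¹, a typical high-yield early-rice level),
  with the same noise model.
* **Reproducibility.** The seed is a required, explicit field of the
  configuration; the caller's RNG stream is untouched.

What the generator deliberately does **not** emulate: weather and soil
processes, within-season growth dynamics, spatial field heterogeneity,
between-variety parameter differences, and measurement error in the N
assay itself. Passing tests on synthetic data therefore demonstrate the
statistical machinery — classification power, construction geometry,
estimator bias — not the agronomic realism of any particular trial.

```{r synthetic-run}
sim <- simulate_experiment(synthetic_config(seed = 1))
pts <- extract_critical_points(sim$table, method = "anova")
fit_curve(pts)
sim$truth$stage
```

## Numerical and design choices

* **Oblique on means.** The oblique line is fitted to treatment means
  (one point per rate), the standard Justes practice and the only option
  for published mean tables; a replicate-level flag exists for users who
  want within-treatment scatter in the fit.
* **Ties.** Treatments exactly tied for maximal mean LDM are all
  non-limited. In the letter rule, multi-letter labels ("ab") share
  membership with every group they name.
* **Degenerate ANOVA.** A date with zero within- and between-treatment
  variance has an undefined F statistic; it is treated as no evidence of
  limitation (all non-limited, unusable) rather than an error.
* **alpha.** Classification and comparison default to 0.05, the level of
  the published letter displays.
* **Fixture year.** The packaged mean table does not state which trial
  year it summarizes; its `year` is left missing, and season-pooled fits
  on it should be read with that ambiguity in mind.
* **Problem sizes.** The test suite validates parameter recovery on 500
  simulated trials (5 stages × 4 rates × 3 replicates), classification
  agreement on 200 simulated dates, and test calibration on 1000 null and
  200 alternative comparisons — sizes at which the Monte-Carlo error of
  the checked rates is well below the asserted margins.

## Known limitations

* Five critical points per variety (one per stage) is the floor for a
  stable power-law fit; single-variety curves from mean-level tables are
  leverage-dominated and should be interpreted cautiously. Pooling
  varieties within a season, as the season-level workflow does, is the
  robust default.
* The letter rule inherits whatever post-hoc procedure produced the
  letters; it cannot be more powerful than the published analysis.
* The NNI band and the yield-response stage are crop- and region-specific
  tuning knobs, not universal constants.
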