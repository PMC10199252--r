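# modulearn

Which facets of psychological distress respond to which kind of contemplative
mental training? `modulearn` is an analysis pipeline for randomized studies in
which cohorts practice different 3-month training modules — mindfulness-based
attention (*Presence*), socio-affective/compassion training (*Affect*),
metacognitive perspective-taking (*Perspective*) — alongside a retest control
cohort (RCC), and a broad battery of self-reported distress questionnaires is
scored before and after each module. The unit of analysis is the **episode**:
one participant's change score vector (post − pre) over a 68-variable,
16-questionnaire distress panel for one 3-month period.

The package is written for applied biostatisticians who want to run, audit or
extend this kind of multivariate "which-training-did-they-do" analysis:

* **Classification engine.** Four classifier families behind one contract —
  logistic regression, random forest, a boosted sum-of-trees ensemble (the
  Bayesian-regression-tree slot), and the elastic net — evaluated by
  **balanced accuracy** `BAC = (sensitivity + specificity) / 2` under
  repeated, group-aware, stratified 10-fold cross-validation (a participant's
  episodes never straddle a train/test split). Per-repetition BACs are tested
  against chance (0.5) with a one-sided Wilcoxon signed-rank test.
* **Four-stage stability selection.** Per-algorithm informativeness cutoffs
  (shadow-variable calibration for the tree ensembles, the inner-CV
  regularization path for the elastic net), a ≥2-of-3 **majority vote**, a
  **bootstrap forward/backward stepwise** refinement scored by median
  out-of-bootstrap BAC of a logistic model, and a replicability criterion:
  variables selected in ≥95% of repeated cross-validation runs form the
  final set.
* **Effect profiles.** Selected variables enter an exemplary logistic
  regression on standardized predictors; each variable is attributed to a
  module via its coefficient and improvement direction, then
  improvement-oriented **Cohen's d** and one-sided Welch tests are computed
  against the other module and the retest cohort. A variable with both
  comparisons significant belongs to the module's *specific effect profile*.
* **Synthetic generator.** The original study data are GDPR-restricted, so
  the package ships a generator for correlated questionnaire change scores
  (block correlation within/between questionnaires, shared participant
  intercepts across periods, planted module-specific standardized effects,
  configurable missingness/dropout) that reproduces the cohort design
  (RCC/TC1/TC2/TC3 = 90/80/81/81 participants). Every pipeline stage is
  testable end to end against planted ground truth.

## Worked example

Simulate a study with the packaged 13-variable specific-effect specification,
cross-validate the Affect-vs-Perspective contrast, and profile a selected set:

```r
library(modulearn)

ds <- simulate_change_scores(effects = default_effect_spec(), seed = 1)
dplyr::count(ds, episode_label)
#> # A tibble: 4 × 2
#>   episode_label     n
#>   <chr>         <int>
#> 1 Affect          242
#> 2 Perspective     161
#> 3 Presence        161
#> 4 Retest          270

res <- analyze_contrast(
  ds, "AffectVsPerspective",
  specs = list(lr = classifier_spec("logistic_regression")),
  n_folds = 10, n_repeats = 10, seed = 1)
glance(res)
#> # A tibble: 1 × 7
#>   spec_id family              filtered median_bac   q25   q75  p_value
#>   <chr>   <chr>               <lgl>         <dbl> <dbl> <dbl>    <dbl>
#> 1 lr      logistic_regression FALSE         0.642 0.639 0.655 0.000977
```

The per-repetition median balanced accuracy (64.2% here) is the headline
metric: 50% is chance for any class mix, and the Wilcoxon p-value says the
repetition BACs sit consistently above it. With the small planted effects
(d ≈ 0.3) the contrast is detectable but far from separable, which is the
regime this design targets.

```r
prof <- build_profile(ds, "AffectVsPerspective",
                      c("pss_total", "tics_lack_social_recognition",
                        "mach_total", "ius_negative_affect_uncertainty"))
dplyr::select(prof, variable_id, module, estimate, d_vs_retest, specific_effect)
#> # A tibble: 4 × 5
#>   variable_id                     module      estimate d_vs_retest specific_effect
#>   <chr>                           <chr>          <dbl>       <dbl> <lgl>
#> 1 pss_total                       Perspective   -0.231       0.188 TRUE
#> 2 tics_lack_social_recognition    Perspective   -0.252       0.217 TRUE
#> 3 mach_total                      Affect         0.399       0.261 TRUE
#> 4 ius_negative_affect_uncertainty Affect         0.339       0.420 TRUE
```

Negative coefficients point to the Perspective module (the positive class),
positive coefficients to Affect. `d_vs_retest` is oriented so positive values
mean more improvement in the attributed module than in the retest cohort;
here the recovered d values scatter around the planted 0.30-0.32 with the
sampling noise a single simulated study implies. `run_selection()` runs the full four-stage
stability selection and `autoplot()` renders the standard BAC boxplots,
selection-rate lollipops and effect-profile panels.

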