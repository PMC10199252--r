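---
title: "Methods: stability-selected classification of training effects on distress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected classification of training effects on distress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
model behind the synthetic data, the classification and inference pipeline,
the four-stage stability selection, the effect-profile construction, and the
numerical and design choices that were genuinely open. It states no
empirical numbers beyond those the package's tests and acceptance script
compute themselves.

## The scientific setting

A randomized mental-training study assigns healthy adults to a retest
control cohort (RCC) or to one of three training cohorts (TC1, TC2, TC3).
Training proceeds in 3-month modules cultivating distinct capacities:
attention and interoception (*Presence*), socio-affective skills such as
compassion (*Affect*), and metacognitive perspective-taking (*Perspective*).
Before and after every module each participant completes a battery of
clinically relevant questionnaires; the analysis works on the 68
**change scores** (post − pre) per episode, where an *episode* is one
participant's single module (or retest) period.

The scientific questions are framed as classification problems over
episodes:

* **Shared effects** — can classifiers tell pooled training episodes from
  retest episodes? (`TrainingVsRetest`)
* **Specific effects** — can they tell *which* module was practiced?
  (`PresenceVsAffect`, `AffectVsPerspective`; Presence and Perspective are
  never counterbalanced against each other in the design, so that direct
  contrast is rejected at construction.)

A classifier that beats chance identifies a multivariate change signature;
the variables that drive it — if they are *stably* selected — constitute a
module's effect profile.

## The distress panel and its conventions

The default panel (`default_panel()`) holds 68 variables grouped under 16
instruments. Each variable carries an `improvement_direction`: `+1` when a
raw-score decrease means improvement (distress-coded scales such as
depression, chronic stress, pain catastrophizing) and `-1` when an increase
does (wellbeing-coded scales: Mental Health Continuum, Satisfaction With
Life). Change scores are stored raw; the direction is applied only when
effect sizes are computed, never at load time. The exact subscale
composition of the original battery is not public, so the packaged panel
distributes standard subscales of the 16 named instruments to total exactly
68; the panel is plain data (`read_panel()`) and can be replaced verbatim.

Analogously, `reported_selection()` packages the variable sets reported to
survive the 95% selection criterion in the two module contrasts (14 and 6
variables). Eleven of the fourteen Presence-vs-Affect variables are named
in the published text; the remaining three are completed with related
facets and flagged `synthetic = TRUE`.

## The synthetic generator

Real data from this study cannot be shared, so `simulate_change_scores()`
generates datasets with the statistical structure the analysis assumes.

**Distribution.** Episode change vectors are multivariate normal. Published
summaries only report means and dispersions per scale, which cannot
discriminate heavier-tailed alternatives; normality is the parsimonious
choice and a heavy-tail option was deliberately deferred.

**Correlation.** Facets of one questionnaire share content, so the panel
correlation is block-structured: `within_questionnaire_correlation` (default
0.4) inside an instrument, `between_questionnaire_correlation` (default 0.1)
across instruments. The defaults make subscales moderately redundant on
purpose — a variable-selection procedure that cannot cope with correlated
predictors is of no use on questionnaire data.

**Within-participant dependence.** All episodes of one participant share a
normal random intercept with variance `0.1 * sd^2` (a tenth of a variable's
residual variance), so group-aware fold assignment is meaningfully
testable. Two calibration details follow from it:

* the *residual* block correlations are adjusted downward
  (`rho_resid = rho * (1 + iv) - iv`) so that the **marginal** correlations
  equal the requested values;
* a planted effect `d` shifts the mean by
  `improvement_direction * (-d) * total_sd`, where `total_sd` includes the
  intercept variance. A planted `d` is therefore exactly a standardized
  mean change relative to retest, and the d-recovery checks
  (0.25 planted → 0.25 ± 0.02 recovered over 1000 replicates) are
  meaningful rather than systematically biased by the intercept term.

**Planted effects.** `default_effect_spec()` plants the 13 reported
module-specific improvements: three Presence effects at d = 0.24, eight
Affect effects at d = 0.30, two Perspective effects at d = 0.32 — midpoints
of the published ranges where per-variable values are not printed. Retest
episodes always have mean zero.

**Missingness.** Cells go missing independently at `missing_rate`;
participants drop out after a uniformly chosen period at `dropout_rate`.
Both default to 0 so that test conditions are explicit. Contrasts handle
missingness by listwise deletion (no imputation), matching a design that
reported modest dropout and no imputation.

**What the generator does not emulate.** Item-level responses, floor/ceiling
effects, ordinal granularity, practice-dose effects, and any systematic
(non-random) missingness. Passing tests demonstrate that the *pipeline*
behaves correctly under the assumed data model, not that real questionnaire
data satisfy that model.

## Classifiers

Four families sit behind one fit/predict contract (`fit_classifier()`),
all deterministic given a seed:

| family | engine | defaults |
|---|---|---|
| `logistic_regression` | `glm.fit`, ridge 1e-6 fallback under separation | unpenalized |
| `random_forest` | `ranger` | 500 trees, √p variables per split, permutation importance |
| `bayesian_regression_tree` | `xgboost` | 50 trees, depth 2, learning rate 0.1 |
| `elastic_net` | `cv.glmnet` | α = 0.5, 5-fold inner CV |

The `bayesian_regression_tree` family is realized as a boosted sum-of-trees
ensemble whose **tree-inclusion proportion** (share of trees whose splits
use a variable) plays the role of a posterior inclusion probability; the
engine is recorded in fit metadata. This keeps the three importance-style
algorithms methodologically distinct — bagged trees with permutation
importance, boosted trees with inclusion frequency, and a sparse linear
model with |coefficient| on its inner-CV path (`lambda.1se`, the
conservative end, chosen so that pure-noise data yield near-empty candidate
sets).

Balanced accuracy is the evaluation metric throughout: the mean of the two
per-class recalls, so 0.5 is chance under any class imbalance (e.g. 161
Presence vs 242 Affect episodes). Class imbalance is handled by the metric
only; training folds are never resampled.

## Cross-validation and inference against chance

`run_cv()` executes `n_repeats` (default 10) independent stratified 10-fold
cross-validations. Folds are assigned at the participant level by a
least-loaded greedy that keeps each fold's class counts within a couple of
episodes of the global proportions, and a hard assertion guarantees no
participant appears on both sides of a split — the conservative choice,
since cohorts like TC1 contribute episodes to both classes of a module
contrast. The per-repetition score is the mean held-out BAC over folds;
per-spec summaries report median, interquartile range, and a one-sided
Wilcoxon signed-rank p-value for median BAC > 0.5 (exact for ≤ 25 untied
values, normal approximation with continuity correction otherwise; an
all-0.5 sample is degenerate and returns p = 1 with a warning).

One property deserves emphasis: the signed-rank test treats repetitions as
exchangeable evidence, but repetitions share the dataset. The test is
therefore exact about "this dataset's cross-validated accuracy exceeds
chance" and anti-conservative about generalization to new studies. That is
a property of the published procedure itself; the package documents it
rather than silently altering the method. The test's size is verified on
independent null accuracies in the test suite.

The default spec set (`default_classifier_set()`) crosses
{logistic regression, random forest} with {filtered, unfiltered} — the four
reported models; the full 4-family × 2 grid is available by passing any
list of specs.

## The four-stage stability selection

Stage 1 (`stage1_candidates()`) computes per-algorithm candidate sets with
scale-free cutoffs. For the two tree ensembles the design matrix is
augmented with 20 row-permuted *shadow* copies of randomly chosen columns;
a real variable is a candidate only if its importance exceeds the largest
shadow importance. Shadows are noise by construction, so their maximum
estimates the upper ≈95% envelope of the no-signal importance distribution
at a twentieth of the cost of refitting under label permutations. The
elastic net's candidates are its nonzero coefficients at `lambda.1se`.

Stage 2 (`majority_vote()`) keeps variables flagged by at least two of the
three algorithms, decoupling the result from any single algorithm's
idiosyncrasies.

Stage 3 (`bootstrap_stepwise()`) refines the candidates by predictive
value: a greedy forward pass adds the candidate that most improves the
median out-of-bootstrap balanced accuracy of a logistic model across B =
100 stratified bootstrap resamples; a backward sweep then removes any
variable whose removal does not reduce the score. All comparisons share one
set of resamples (common random numbers) and ties break lexicographically,
so the stage is deterministic given its seed. Numerical choices: the
logistic fits are ridge-stabilized (1e-6) IRLS; per-resample fits take two
capped Newton refinements from the full-sample optimum, which is enough to
rank models by OOB accuracy since predictions depend only on the sign of
the linear predictor. A forward addition must beat the current score by
`max(0.005, 2 × SE(median))`, the standard error estimated from the
bootstrap distribution itself. A fixed zero tolerance would admit a
pure-noise variable about half the time — the median's Monte-Carlo jitter
at B = 100 straddles zero — so the bar scales with the score's own
uncertainty; the backward sweep uses no tolerance, so a variable with any
genuine contribution survives it.

Stage 4 (`run_selection()`) wraps stages 1–3 in `n_repetitions` independent
stratified 10-fold cross-validations (the study criterion uses 200; the
package's acceptance checks use 20 for tractability and state so). Within a
repetition a variable counts as selected when a majority of the 10 folds
select it (an "any fold" alternative is a flag); its **selection rate** is
the fraction of repetitions selecting it; the final set holds variables
with rate ≥ τ = 0.95. Seeding is counter-based: a master seed spawns one
child per (repetition, fold, purpose), so runs are reproducible and
order-independent, and permuting input columns permutes the trace exactly.

### What stability selection can and cannot recover

Two structural facts about this class of procedures surface clearly on
synthetic data and matter for interpretation:

* **Suppressor variables are genuinely predictive.** An unplanted facet
  that shares questionnaire-level noise with a strongly planted facet
  improves classification when conditioned on (it whitens the shared
  noise), so predictiveness-driven selection can stably include variables
  with no marginal effect of their own. This is correct behavior of the
  Bayes-optimal classifier, not a bug; it means a selected set should be
  read as "jointly discriminative", not "each marginally affected".
* **Greedy saturation bounds the set size.** Once many strong variables
  are in the model, the marginal accuracy gain of the next one falls below
  any jitter-robust improvement bar, so the weakest true effects in a
  large planted set are excluded. With independent noise the procedure
  recovers small planted sets exactly (unit-tested); under the default
  correlated panel, recovery of a 14-variable planted set is partial by
  construction. The acceptance suite asserts the exact-recovery criterion
  at the stated study conditions and reports its outcome honestly.

## Effect profiles

`build_profile()` turns a selected set into interpretable output. An
unpenalized logistic regression on z-standardized predictors (so
coefficients are comparable across facets) provides the exemplary
coefficients; under quasi-separation it falls back to a tiny ridge with a
flagged warning and reports standard errors from the penalized information
matrix. The positive class of a module contrast defaults to the
first-named module, the coding under which *negative* coefficients of
distress-coded variables point to that module.

Attribution is improvement-oriented: a variable belongs to the module
toward which its improvement direction points, i.e. to the positive class
when `-improvement_direction × β > 0`. For each variable the package then
computes Cohen's d (pooled-SD, `n_a + n_b - 2` denominator) and a
one-sided Welch test (Satterthwaite degrees of freedom; Student's pooled
variant by flag) against (i) the other module's episodes and (ii) retest
episodes from the same study periods in which the attributed module was
practiced (`retest_window = "matched"`; first-period-only by flag). Both d
values are oriented so positive means more improvement in the attributed
module. A variable with both one-sided p-values below α = 0.05 carries
`specific_effect = TRUE`. No multiplicity correction is applied by default,
matching the reported analysis; Benjamini–Hochberg is a flag.

## Problem sizes used by the packaged checks

The acceptance suite runs the null-calibration check at the full design
(10 × 10-fold CV on 332 first-period episodes), the d-recovery check at
1000 replicates of 161-vs-90 episodes, and the planted-set recovery at 20
selection repetitions per contrast; unit tests use smaller toys (tens to a
few hundred episodes, 5–20 variables) chosen so each property is decidable
in seconds. The acceptance script regenerates the d-recovery quantity from
scratch with seeds derived from its `--seed` argument.

## Known limitations

* Normal, homoscedastic change scores; ordinal and skewed scales are not
  emulated.
* The Wilcoxon-against-chance inference is dataset-level (see above).
* The selection procedure characterizes jointly discriminative sets;
  marginal-effect claims require the post-hoc effect-size stage, which is
  why the specific-effect flag demands significance against *both*
  comparators.
* The packaged panel and the three unnamed members of the fourteen-variable
  reported set are synthetic completions and are flagged as such.
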