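---
title: "Predicting take-over success from ability profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting take-over success from ability profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(takeovr)
```

## The problem

In conditionally automated (SAE Level 3) driving, the vehicle may request
that the driver take back control with only a few seconds' warning. Whether
a driver completes such a critical take-over without a collision is a
binary outcome, and an applied question is whether it can be predicted from
abilities measured *outside* the vehicle: visuo-attentional test scores
(visuomanual tracking, multiple-object avoidance and tracking), executive
test scores (n-back, Corsi block tapping, stop-signal, flanker,
trail-making, Tower of London) and biographical data (age, mileage, licence
years). takeovr implements that analysis pipeline end to end on a
participants × abilities matrix paired with a 0/1 success vector.

The reference configuration is a cohort of 113 participants and 15
predictors, with 63 successes; `default_ability_catalogue()` lists the 15
variables with their tasks, units, and orientations.

## Data model

Two conventions make the downstream algebra uniform:

* **Orientation.** Each catalogue variable carries a flag in {+1, −1};
  `orient_abilities()` multiplies each column by its flag so that a larger
  value always means a higher ability. Five variables are negatively
  oriented (reaction-time differences, the stop-signal reaction time,
  unnecessary moves), and become negative-valued after orientation. The
  operation is an involution, and flipping a flag negates exactly that
  standardized column.
* **Standardization.** Predictors are centred and scaled with the sample SD
  (divisor $n-1$), so coefficients are per-SD and comparable across
  abilities with different units. Inside cross-validation the means and SDs
  are recomputed on each training fold and applied to the held-out row —
  the held-out participant never influences their own standardization.
  Missing values are rejected at load time (`read_abilities()`); the
  analysis assumes a complete matrix and no imputation is offered.

## PLS logistic regression

Ordinary ML logistic regression is unstable when predictors are correlated
and $p$ is large relative to $n$; partial least squares builds a small
number of outcome-informed components instead. For a binary outcome the
construction (implemented in `fit_pls_logistic()`) is:

1. $w_1 \propto$ the slopes of the $p$ univariate logistic regressions of
   $y$ on each standardized $x_j$, normalised so $\lVert w_1 \rVert = 1$;
   $t_1 = X w_1$.
2. For $h \ge 2$: each $x_j$ is deflated by OLS on $t_1, \dots, t_{h-1}$;
   the weight of $x_j$ is its coefficient in a logistic regression of $y$
   on $(t_1, \dots, t_{h-1}, \tilde x_j)$; weights are normalised and
   $t_h = \tilde X w_h$. Deflated columns are exact OLS residuals, so the
   components are mutually orthogonal in sample (tested to $10^{-8}$).
3. A final logistic regression of $y$ on $t_1, \dots, t_H$ gives
   $\gamma_0, \gamma$. Adjusted weights $w^*_h$ (absorbing the deflation
   recursively) express every component over the original standardized
   predictors, giving $\beta = W^* \gamma$ with
   $\gamma_0 + \sum_h \gamma_h t_h \equiv \gamma_0 + x^\top \beta$ —
   an identity the test suite asserts on every fit.

With $H = p$ on full-rank data the components span the predictor space and
the fit reproduces the ML logistic fit exactly; the suite checks this
against `glm()` to $10^{-4}$ on twenty fixtures. A column whose deflated
version is numerically zero gets weight 0 — it carries no information
beyond earlier components.

**Interpretation.** $\exp(\beta_j)$ is the success-odds multiplier for a
1-SD increase in ability $j$; `interpret_coefficient()` reports the percent
change rounded to the nearest integer (0.35 → +42%, −0.42 → −34%,
−0.36 → −30%). Percent changes are computed from the supplied coefficient,
so values printed elsewhere from unrounded coefficients can differ by a
point from the exp-transform of their rounded display.

### Inner solver and separation

All logistic fits use a Newton/IRLS solver: convergence when the largest
coefficient step falls below $10^{-8}$, at most 100 iterations, weights
floored at $10^{-10}$. The univariate fits of step 1 — the hot loop of
leave-one-out evaluation — run column-parallel with closed-form 2×2 solves.

Quasi-separated fits (possible in small leave-one-out folds, and by
construction when a predictor separates the classes) do not converge under
plain Newton. Such fits are retried with a ridge added to the normal
equations — penalising gradient and Hessian so the iteration targets the
finite ridge optimum — starting at $10^{-6}$ and escalating to $10^{-4}$
and $10^{-2}$ only if needed, with Newton steps capped at 10 in sup-norm so
the saturated region cannot throw the iteration. Stabilized fits are
flagged on the model object. Predicted classes in separated cases are
unaffected: the stabilized coefficients are large and the probabilities
saturated on the correct side.

## Model selection

**Error accounting.** A *false positive* predicts success for a participant
who collided; a *false negative* predicts failure for one who succeeded.
Classification uses a 0.5 threshold with the boundary assigned to success.
Under leave-one-out, each participant is predicted by a model fitted to the
other $n-1$ rows with fold-local standardization.

**Minimax.** Candidates (component counts in `select_n_components()`,
predictor subsets in `exhaustive_subset_search()`) are ranked by
$\max(\mathrm{FP}, \mathrm{FN})$, ties broken by total errors. Beyond those
two stated criteria a deterministic artifact needs a total order, so the
cascade continues: fewer predictors, then smaller $H$, then lowest subset
bitmask. The criteria actually consulted are recorded in a tie-break audit
attribute. Balancing the two error types (rather than minimising their sum)
reflects that a collision predicted as success and a success predicted as
collision have different practical costs and neither should dominate.

**Exhaustive search.** All $2^p - 1$ non-empty subsets are evaluated —
32,767 models in the 15-predictor reference configuration. The enumeration
cap defaults to $p \le 20$ and must be raised explicitly beyond that. $H$
is passed as an argument and capped at the subset size; the reference
analysis fixed $H = 1$ from the component-count step before searching
subsets, and the package follows that usage. Fold standardizations are
cached across subsets (standardization is per-column, so subsetting cached
fold matrices is identical to the naive loop — asserted against an
independent scripted LOO in the tests). Subsets whose evaluation fails
(e.g. a single-class training fold) are marked ineligible rather than
imputed. Subset evaluations are independent, so they could run
concurrently; the implementation is serial and the cache keeps the
reference scale tractable.

**A note on component counts.** On synthetic single-latent cohorts the
$H = 1$ and $H = 2$ leave-one-out counts usually sit within one or two
errors of each other: the first PLS component is built from univariate
slopes, which are differentially attenuated across predictors, and the
second component corrects that toward the full ML fit. Selection between
them is therefore often decided by the tie-break, just as the reference
analysis's own component table tied on the Minimax criterion and fell back
to totals. The tests assert Minimax-consistency of the selection and a
parsimonious outcome rather than a universal "$H = 1$ wins".

## Permutation robustness

`permutation_robustness()` asks whether the selected model's performance
could arise from chance associations. Default behaviour: every predictor
column is shuffled independently (breaking predictor intercorrelations as
well as predictor–outcome links), the same model specification is refitted
on the shuffled data, and its in-sample misclassifications are compared
with the unshuffled model's. The reference analysis used 10,000
permutations; tests and the acceptance script use 200–500. Two documented
alternatives sit behind switches: `shuffle = "joint"` permutes whole rows
of the predictor block (preserving intercorrelations), and
`mode = "freeze"` scores shuffled inputs with the baseline coefficients
instead of refitting. Refitting is the default because the comparison of
interest is against *permuted-data models*, i.e. what the pipeline would
have found had the predictors carried no information. One seeded stream
drives the permutations, so extending the run leaves earlier draws
unchanged; degenerate refits are recorded as failed permutations and
excluded from summaries.

## Test scoring

Trial-level records are reduced to the predictor-level scores of the
catalogue:

* **SSRT, integration method** (`ssrt_integration()`): go RTs ranked
  ascending with omitted go trials replaced by the maximum observed go RT;
  the $n$-th RT is taken at $n = \lceil p \cdot n_{go} \rceil$ where $p$ is
  the probability of responding on a stop trial; SSRT is that quantile
  minus the mean stop-signal delay. The ceiling convention is the
  conservative choice when $p \cdot n_{go}$ is fractional; go errors are
  retained as responses. $p = 0$ leaves SSRT undefined and errors.
* **Difference scores** (`difference_score()`): hard minus easy/calibration
  condition (3-back − 1-back, incongruent − congruent, TMT-B − TMT-A).
* **Tracking closeness** (`percent_time_close()`): percent of samples at or
  below the threshold (default 0.5 cm), boundary inclusive.
* **Span** (`span_score()`): highest level passed, 0 if none.

Trial aggregation (e.g. mean avoidance time over six trials) is a plain
arithmetic mean; the multiple-object-tracking speed threshold is produced
by its commercial software and enters as a pre-computed column.

## The synthetic cohort generator

`simulate_cohort()` draws predictors from a zero-mean, unit-variance
equicorrelated multivariate normal — a single shared factor
$x_{ij} = \sqrt{\rho}\, g_i + \sqrt{1-\rho}\, \varepsilon_{ij}$, giving the
exact common correlation $\rho$ — and the outcome from
$\mathrm{Bernoulli}(\mathrm{logistic}(\alpha + x_i^\top \beta))$.
`intercept_for_rate()` solves $\alpha$ by quadrature plus root-finding so
the expected success rate equals the target (the linear predictor is
Gaussian with variance $(1-\rho)\sum\beta_j^2 + \rho(\sum\beta_j)^2$).
Defaults are the reference conditions: $n = 113$, $p = 15$, success rate
$63/113$, five active predictors carrying $(+0.45, +0.35, +0.22, -0.42,
-0.36)$ on the Corsi-span, visuomanual-coordination, annual-mileage,
stop-signal and flanker-accuracy columns, and $\rho = 0.2$ — a moderate
positive intercorrelation typical of cognitive test batteries.

What the generator emulates: the matrix shape, the orientation convention,
a realistic base rate, correlated predictors, a one-component generative
structure with mixed-sign effects. What it does not: real test-score
distributions (several are bounded, discrete or skewed; the generator is
Gaussian), a full empirical 15×15 correlation matrix (a single $\rho$ is
used; the option is configurable), or raw measurement units (columns are on
the standardized scale). Passing tests on synthetic cohorts therefore
demonstrates that the machinery recovers known structure under the stated
model, not that any particular real dataset would yield the same tables.

Two calibration notes. First, the default effect sizes are the selected
model's published per-SD coefficients; those are attenuated one-component
estimates, so cohorts generated from them carry a somewhat weaker signal
than the data they were estimated from (in-sample accuracy ≈ 0.65 at
$n = 113$ versus the published 0.708). Second, for that reason the
strong-signal permutation demonstrations use twice those magnitudes, a
condition under which shuffled refits essentially never match the real
model; at the default magnitudes a small fraction of permutations can tie
the baseline, which is informative about the method rather than a defect.

## Reporting

`univariate_comparisons()` runs one pooled-variance Student t-test per
ability (equal-variance, $df = n_1 + n_2 - 2 = 111$ in the reference
configuration — the pooled form is what reproduces that df). No
multiple-testing correction is applied, matching the exploratory intent;
the column is named `p_uncorrected` and the report labels it so.
`confusion_metrics()` reports accuracy $100(a+d)/n$ and two rates named
carefully: the reference analysis calls $100a/(a+b)$ — success predicted
among actual successes — the model's *specificity*, and $100d/(c+d)$ its
*sensitivity*, which swaps the usual epidemiological convention; the
package uses the neutral names `success_prediction_rate` and
`fail_prediction_rate`. `final_report()` assembles the component table,
subset-search summary, confusion matrix, per-SD coefficient table with
units, permutation summary and univariate table into one JSON-serialisable
object; absent stages render as "not run".

## Numerical and design choices

* Newton/IRLS tolerance $10^{-8}$ on coefficient steps, 100 iterations;
  ridge ladder $10^{-6}, 10^{-4}, 10^{-2}$ on separation; step cap 10.
* Classification threshold 0.5, boundary to success.
* SD divisor $n - 1$ everywhere, matching per-SD coefficient units.
* Tie-break cascade: max errors, total errors, fewer predictors, smaller
  $H$, lowest bitmask.
* Model serialization at 17 significant digits (`write_pls_model()`), so a
  JSON round trip is exact to printed precision.
* Problem sizes in the test suite and acceptance script are scaled to keep
  full runs quick while preserving the structure: subset search over
  $p = 8$ (255 models × 150 folds), permutations 200–500, sign-recovery
  sweep over 50 seeds at $n = 500$. The full $p = 15$ search (32,767
  subsets × 113 folds) runs with `max_predictors = 15` in well under an
  hour on one core.

## Limitations

* Binomial outcomes only; no general exponential-family PLS and no sparse
  PLS variant.
* No significance-based pruning inside component construction — subset
  selection is the explicit, exhaustive outer loop.
* The permutation null is purely empirical; no analytic approximation is
  offered.
* Leave-one-out Minimax counts are integers with sampling noise of a few
  errors at reference scale; near-ties between adjacent component counts or
  overlapping subsets are expected and resolved deterministically, not
  statistically.
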