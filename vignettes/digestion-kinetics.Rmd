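---
title: "Digestion kinetics and eGI prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digestion kinetics and eGI prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchdx)
```

## The measurement and its model

An in vitro digestion run samples the cumulative percent of starch
hydrolysed at 0, 15, 30, 45, 60, 90 and 120 minutes of the intestinal
phase (t = 0 at simulated intestinal fluid addition). Hydrolysis is
measured as reducing sugar released (DNS assay read at 520 nm against a
0–1 mg/mL glucose standard line) and converted to percent of total starch
by

$$\mathrm{SH}(\%) = \frac{G_t \times 0.9}{TS} \times 100,$$

the factor 0.9 = 162/180 being the anhydroglucose mass ratio that folds
free glucose back into polymeric starch equivalents.

Between samples the curve is treated as piecewise linear: interpolation is
linear (`value_at()`), the AUC is the composite trapezoid rule
(`auc_trapezoid()`), and extrapolation beyond the sampled range is always
refused — with seven points per curve there is no defensible basis for it.

As a smooth summary the package fits the first-order
(exponential-plateau) model

$$C(t) = C_0 + (C_\infty - C_0)\,\bigl(1 - e^{-kt}\bigr),$$

the standard description of enzymatic starch digestion: a fast initial
phase governed by the rate constant $k$ (min⁻¹) approaching an asymptotic
extent $C_\infty$ set by the digestible starch fraction. The model assumes
a single well-mixed substrate pool with constant enzyme activity; it cannot
represent lag phases (sigmoidal onsets) or biphasic digestion of mixed
rapidly/slowly digestible starches.

## The two eGI predictors

The single-point predictor uses only the 90-minute hydrolysis value
$H_{90}$:

$$\mathrm{eGI} = 39.21 + 0.803 \times H_{90}.$$

The kinetic + macronutrient predictor combines curve shape with
composition (g/100 g):

$$\mathrm{eGI} = A + \frac{S_{60}}{S_{120}}\,HI
  - 0.26\,\mathrm{Protein} + 0.54\,\mathrm{Fat} - 0.43\,\mathrm{Fiber},$$

with $A = 30$ when carbohydrate content strictly exceeds 55 g/100 g and
$A = 15$ otherwise. All coefficients are fixed published constants,
collected in `egi_coefficients()` and overridable there; the package makes
no attempt to refit them.

Three readings in this formula were genuinely open and are fixed as
package design choices:

- **HI normalization.** The hydrolysis index is "the AUC of hydrolysis
  versus time", but raw AUC on this grid is of order 10³–10⁴ %·min, while
  the formula's other terms are of order 10. The default reference is
  therefore the ideal instantaneous-digestion curve (constant 100 % over
  the window), giving $HI = AUC / (120 \times 100) \times 100 \in [0, 100]$
  — the only scale consistent with plausible eGI magnitudes. An explicit
  reference curve (e.g. white bread digested alongside the samples) can be
  passed for the classic food-relative HI.
- **S60 and S120** are read as cumulative percent hydrolysed at 60 and
  120 min, not instantaneous derivatives: derivative ratios would be
  dimensionally inconsistent with HI's scale and numerically unstable on a
  7-point grid. For any monotone curve $S_{60}/S_{120} \le 1$, so the
  kinetic term never exceeds HI.
- **Operator precedence** is $(S_{60}/S_{120}) \times HI$. No worked
  per-food computation exists to confirm it from published numbers, so the
  formula's implementation is certified instead by the property suite
  (below).

The boundary case carbohydrate = 55.0 maps to $A = 15$, a literal reading
of "exceeds"; the threshold is configurable.

## Validation statistics

Predictions are compared to human GI by the per-food deviation
$(GI - \mathrm{eGI})/GI \times 100$ (positive = under-prediction) and by
OLS regression with Pearson correlation. The regression orientation is
fixed as x = human GI, y = eGI: this is the orientation under which the
published 14-food panel statistics (slope 0.7573 / r 0.83 for the
single-point formula; slope 0.9519 / r 0.93 for the kinetic formula)
reproduce exactly from the packaged table, verified against a
normal-equations oracle before the convention was frozen. Slopes are
reported to 4 decimals, intercepts to 2, r to 2 in tabular output; raw
values are retained everywhere else. No confidence intervals or p-values
are computed.

## The synthetic-data generator

`simulate_curve()` evaluates the first-order model on the sampling grid
and adds independent Gaussian measurement noise per replicate, clamping to
[0, 100]. The defaults encode the study conditions the package targets:

| parameter | default | unit | why |
|---|---|---|---|
| `times` | 0, 15, 30, 45, 60, 90, 120 | min | the intestinal-phase sampling grid |
| `noise_sd` | 2 | % points | typical replicate spread of a DNS assay; no measured replicate SD is published, so this is a stand-in |
| `n_replicates` | 3 | — | triplicate assay practice |
| `k` (presets) | 0.03 | min⁻¹ | mid-range digestion rate: ~97 % of the plateau is reached within the 120-min window |

Twelve scenario presets encode the measured cereal conditions
(rice/corn/millet × small/large grain × dynamic/static model) by their
hydrolysis endpoints. The 120-min target pins one equation in two unknowns
($C_\infty$, $k$); the package fixes $k = 0.03$ min⁻¹ and solves
$C_\infty = C_0 + (\mathrm{target} - C_0)/(1 - e^{-120k})$, so the
noiseless curve passes through both endpoints exactly. Where no 0-min
value was measured (corn, millet, large-grain rice), $C_0$ defaults to 5 %
and the preset carries `c0_assumed = TRUE`.

`simulate_food_panel()` draws compositions uniformly over the ranges a
mixed food panel spans (carbohydrate 3–95, protein 0–36, fat 0–22, fiber
0–10 g/100 g) and kinetics ($C_0$ 2–15 %, $C_\infty$ 20–98 %, $k$
0.01–0.06 min⁻¹) chosen once so the hydrolysis index spreads over roughly
10–90. Each food's *true* eGI is the kinetic formula evaluated on its
noiseless curve, and human GI is that truth plus Gaussian noise (SD 5 GI
units, the order of inter-study GI variability), floored at 1 to keep GI
positive — under these ranges the true eGI stays above ~5, so the floor
essentially never binds.

Two caveats on what passing tests show. First, noise enters the simulated
*human GI*, i.e. the regression's x variable, so OLS recovery of the unit
slope is attenuated by the classical errors-in-variables factor
$\mathrm{var}(\mathrm{eGI}) / (\mathrm{var}(\mathrm{eGI}) + \sigma^2)$;
with the default spreads this is ≈ 0.95, which is why the recovery test
accepts slopes in [0.95, 1.05] rather than exactly 1. Second, the
generator emulates only what the analysis assumes — first-order kinetics,
additive Gaussian noise, independent replicates. Real digesta violate all
three in places (lag phases, heteroscedastic assay error, shared batch
effects), so green tests certify the arithmetic of the pipeline, not the
biological adequacy of the first-order model for any particular food.

## Numerical choices

- **First-order fitting** is bounded Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) with $C_0, C_\infty \in [0, 100]$,
  $k \in [0, 1]$ min⁻¹, from a fixed deterministic multi-start: $C_0$ at
  the first observed value, $C_\infty$ at the last, $k \in \{0.005, 0.02,
  0.05\}$ min⁻¹ (spanning slow to fast digestion on this grid). The
  lowest-RSS convergent start wins; ties cannot occur in practice and
  would resolve to the earlier start. Convergence tolerances are set tight
  (`ftol = ptol = 1e-14`) so noiseless parameter recovery reaches ~1e-15
  relative error.
- **Degenerate inputs.** A constant curve leaves $k$ unidentified: it is
  returned as 0 with the `k_indeterminate` flag, not an error. The box
  bounds cannot express $C_0 \le C_\infty$ jointly; a decreasing fit is
  kept but flagged `decreasing_fit`. Fitting requires ≥ 4 points spanning
  ≥ 60 min.
- **Value clipping.** Hydrolysis values in (100, 102] or [−2, 0) —
  assay-noise overshoot — are clipped into [0, 100] with a warning;
  anything beyond ±2 is rejected as a probable unit error.
- **Replicates** are averaged pointwise on their common grid before any
  metric is extracted (grids must match exactly); metrics of an average
  are not averages of metrics for the nonlinear summaries, and the
  averaged-curve convention matches mean-of-triplicates reporting.
- **Randomness.** Every simulator entry point requires an explicit seed
  and restores the caller's RNG state on exit; identical inputs give
  byte-identical output.

## What the test suite computes

The property suite certifies the pipeline end to end: trapezoid AUC equals
segment-wise symbolic integration on random 3–8-point curves; OLS matches
the normal-equations oracle to 1e-10; noiseless simulate → fit round-trips
recover $(C_0, C_\infty, k)$ to 1e-6 relative; the generator's true eGI
equals the pipeline's recomputed eGI to 1e-9 on a 14-food noiseless panel;
and $k$ is recovered with mean absolute error < 0.005 min⁻¹ from 200
noisy replicates (SD 2 points). Monte-Carlo sizes (200 fit replicates,
500 mean-convergence replicates, 200-food recovery panel) keep each
property comfortably stable at the asserted tolerance while the whole
suite runs in a few seconds.

## Known limitations

- The first-order model has no lag phase; strongly sigmoidal curves fit
  poorly (visible as large RSS) and their fitted $k$ should not be
  interpreted.
- The packaged 14-food panel carries the published eGI values, not the
  underlying hydrolysis curves — those inputs were never published — so
  the panel validates the regression and deviation machinery, not the eGI
  formulas themselves; formula correctness rests on the property suite.
- Human GI reference values are transcribed as printed; the upstream food
  composition table was not consulted independently.
- Gastric-phase kinetics, pH trajectories, enzyme-activity decay, particle
  size and intragastric pressure are experimental observables outside this
  package's computational scope.
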