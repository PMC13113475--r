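---
title: "Combining published enteric methane prediction equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining published enteric methane prediction equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4combine)
```

## The problem

Enteric methane from dairy cattle is usually estimated, not measured:
respiration chambers and tracer techniques are expensive, so practitioners
rely on published prediction equations that map feed intake and diet
composition to daily emissions. Many such equations exist, built on
different herds, measurement methods and regions, and they disagree
substantially on the same ration. `ch4combine` treats the published
equations themselves as data: it evaluates a curated library of 32
equations (from five source publications) over a set of diets, and fits a
mixed model to the resulting prediction table to obtain one *combined*
equation representing the average published relationship, together with an
explicit estimate of how much the literature disagrees.

## The equation library

Each registry record stores an intercept, a list of terms
`(coefficient, variable, unit)`, a shape, and an output unit. Two shapes
occur: a plain linear form, and a linear form multiplied through by dry
matter intake (DMI, kg DM/day). Outputs published as MJ CH4/day are
converted to g/day using the energy content of methane, 55.65 kJ/g
(i.e. division by 0.05565 MJ/g). Variables are resolved at the unit each
source publication used: DMI in kg DM/day, metabolisable energy intake
(MEI) in MJ/day, nutrient concentrations in % of DM, or daily nutrient
intakes derived as `pct/100 * DMI`.

Unit assignment is the single riskiest transcription decision, because the
source table does not restate units per equation. The registry follows the
assignments that produce plausible magnitudes for dairy diets — the
Ellis rows take fibre as daily intake (kg/day) with MJ/day outputs, the
Van Lingen, Moate and Niu rows take concentrations with g/day outputs, and
the Nielsen rows convert MJ/day outputs with concentrations — and a
unit-audit test asserts that every per-kg-DM prediction on the packaged
diets falls in a broad plausibility window of 5–45 g CH4/kg DM, so a
mis-assigned unit (which typically shifts results by an order of
magnitude) cannot pass silently. One row (Ellis 7d) is printed without
parentheses in its source; it is evaluated with the printed operator
precedence, converting only its fibre term, because the all-terms reading
yields physically impossible emissions (an order of magnitude above any
other equation). The published duplicate pair (Niu 27/29) is kept verbatim
to preserve the library's weighting of that functional form.

Negative predictions are possible on extreme inputs (one equation has
intercept −48.5); they are returned with a warning rather than clamped,
since clamping would bias ensemble statistics.

## Completing the withheld intake variables

Ration composition tables typically publish nutrient concentrations and
MEI but not DMI, and therefore neither ME concentration (`MEI/DMI`), gross
energy, nor ash. These are completed synthetically, with every choice
seeded and recorded:

* **DMI** is drawn uniformly within cohort bounds — lactating 18–24,
  dry 10–14 kg DM/day, typical of UK commercial herds — and then blended
  with a deterministic within-bounds assignment that increases with NDF
  rank. The blending weight is chosen by grid search so that the realised
  `cor(ME, NDF)` across diets hits a target of −0.68 (±0.02 internally;
  an error is raised beyond ±0.05). The target corresponds to a variance
  inflation factor `1/(1 − r²) ≈ 1.87` for the ME + NDF model, i.e.
  moderate, realistic energy–fibre collinearity. A blend of a random and
  a monotone component was preferred over an energy-requirement model for
  DMI because requirement models would import assumptions about milk
  yield and live weight that composition tables do not support; the
  blend is transparent, bounded and exactly reproducible.
* **GE** is generated as `ME + 6.5` MJ/kg DM. The constant offset makes
  GE and ME exactly collinear (r = 1.00), matching how the two behave as
  interchangeable energy proxies in ration data, and makes the GE-based
  candidate models well-defined without pretending to independent
  information.
* **Ash** defaults to 7.5 % DM (a typical dairy TMR value); only one
  equation in the library uses ash, so results are insensitive to it.

The completion never alters a measured field. Because the true intake
values behind the published analysis are not available, downstream fitted
coefficients are *not* expected to reproduce the published ones exactly;
the package's claims at that level are structural (see "What the tests
show" below).

The fully synthetic generator (`generate_synthetic_diets()`) draws
compositions with marginal ranges matching the packaged diets (NDF 32–53
% DM, CP 12–23, EE 2.7–6.5, FA 0–7.5), ADF tied to NDF as
`0.82·NDF ± 0.08` (reproducing the near-perfect NDF–ADF correlation of
real rations), and MEI decreasing in NDF (slope −4 MJ/day per % NDF,
noise SD 35 MJ/day — weak enough that the DMI calibration retains room to
reach the correlation target). It exists so that every downstream stage
can be tested at arbitrary sizes without any external data.

## Standardization, fitting and back-transformation

Predictors are centred and scaled over the long table (sample SD with the
n−1 denominator over all prediction records; for the packaged design the
15 diet values stacked 32 times). The response is never standardized, so
the standardized-model intercept remains the grand mean of the response
on its natural g CH4/kg DM scale.

The mixed model is fitted by REML via `lme4::lmer` with a single random
intercept per source equation. REML is used for its unbiased variance
components; random slopes are deliberately not offered — with predictions
nested in equations the slope information comes from only 15 diets, and
equation-specific slopes add instability without substantive gain.
Raw-scale coefficients are recovered exactly:

$$\beta_{j,\mathrm{raw}} = \beta_j^* / \mathrm{SD}(X_j), \qquad
\beta_{0,\mathrm{raw}} = \beta_0^* - \sum_j \beta_j^* \bar X_j / \mathrm{SD}(X_j).$$

Fitting on raw predictors directly and standardize–fit–back-transform are
algebraically equivalent for this model family; the test suite verifies
agreement to 1e−6, and the package uses the standardized route by default
for optimizer conditioning.

Reported metrics: R² is the squared Pearson correlation between
observations and fitted values *including* the random intercepts (the
model's job is to track equations, not only the fixed plane); RMSE is the
root mean squared residual on the same fitted values; both variance
components are always reported, since a single "residual variance" number
is ambiguous in this design.

Numerical choices: the default `nloptwrap` optimizer is used; a fit is
flagged non-converged on a genuine optimizer failure, while the
roundoff-limited stop (NLOPT code −4, reachable only on noise-free
degenerate data where the optimum is at machine precision) is accepted,
and `lme4`'s post-fit gradient heuristics are recorded but not treated as
failure (they false-alarm on such degenerate fits). A variance component
below 1e−8 is flagged as a boundary fit.

## Candidate models and selection

Variables are screened pairwise at |r| > 0.75 on the diet-level values;
correlated groups keep one representative (NDF over ADF, ME over GE).
Twelve candidate combinations of the survivors are fitted. Selection uses
the |t| > 2 screen on every slope (t = estimate/SE; no degrees-of-freedom
approximation is applied, since with 480 records the reference
distribution is effectively normal and the screen is deliberately
coarse), then parsimony, then RMSE, then ME-over-GE preference. If no
candidate passes the screen the best-RMSE model is returned explicitly
flagged.

## Validation

*Leave-one-diet-out cross-validation.* Each diet is held out; the model
is refitted on the rest; held-out records are predicted as the raw-scale
fixed part plus the training random intercept of each equation (the
equations are the same groups in both halves). Per-diet
R² = 1 − SSE/SST, so the yardstick within a held-out diet is the
between-equation spread for that diet; squared correlation is available
as an option. Aggregates are computed over converged refits only.

*Leave-one-equation-out sensitivity.* Each source equation is removed in
turn and the model refitted; the tabulated raw coefficients show whether
any single publication drives the combined equation. The reported ranges
always include the full-data coefficients.

Dry-cow diets are included by default (they widen the covered predictor
space) with a switch to exclude them; predictions for dry cows sit at the
boundary of the design and deserve caution.

## What the tests show — and what they do not

The simulation tests generate prediction tables from the package's own
generative model at the study design (32 equations × 15 diets, truth
3.47 + 0.33·ME + 0.31·NDF, both SDs 1.5) and verify: raw-scale slopes
within 3 SE of truth in ≥ 90% of 100 seeded replicates; the equation
variance component recovered within 3 Monte-Carlo SEs; collapse to pooled
OLS when the equation variance is zero (agreement 1e−4); perfect fit and
perfect cross-validation on noise-free data. The expected cross-validated
mean R² under these conditions is about
`1 − σ²/(σ²_eq + σ²) ≈ 0.5` minus shrinkage and extrapolation losses;
a three-seed average is checked against the derived envelope 0.30–0.65.

These tests validate the estimation machinery, not the biology: the
generator produces exactly the model the fitter assumes (linear fixed
effects, Gaussian exchangeable intercepts, homoscedastic noise), whereas
real published equations differ in functional form and the real response
surface need not be linear in ME and NDF. Likewise, because the original
intake values are withheld, the packaged-data results (combined
coefficients, CV statistics, sensitivity ranges) are the package's own
under the documented completion settings, deliberately not tuned to match
the published values — though they land close in both magnitude and
pattern, including the dry-cow diets showing the weakest cross-validated
fit.

## Problem sizes

The packaged analysis is 480 records; the recovery study uses 100
replicates at that size; cross-validation refits 15 models and the
sensitivity analysis 32. All of it runs in well under a minute on one
core, which is why no larger designs are exercised by default.

## Known limitations

* The registry transcribes printed coefficients; per-equation unit
  metadata is a documented editorial decision audited by magnitude, not
  recovered from the original five publications' full texts.
* The completion module emulates plausible UK dairy intakes; it cannot
  recover the confidential values, so packaged-data coefficient estimates
  carry that additional, unquantified uncertainty.
* One grouping factor only (equation); no random slopes, no crossed or
  nested designs.
* Diet coverage is temperate-ration shaped; extrapolating the combined
  equation to tropical forages or maize-heavy TMRs is not supported by
  the packaged design.
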