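---
title: "Factorial optimization of forced-degradation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial optimization of forced-degradation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degopt)
library(dplyr)
```

## The problem

Stability-indicating assay development needs stressed samples with a useful,
moderate amount of degradation (typically 5–20% of the drug lost): too little
and the method's specificity cannot be demonstrated, too much and secondary
degradation obscures the primary products.  Finding stress conditions that
hit such a window by trial and error is slow.  `degopt` implements the
systematic alternative: treat the stress variables — here the strength of the
acid or alkali, the reflux temperature, and the heating time — as factors of
a two-level full factorial experiment, model % degradation as the response,
screen which factors matter, and invert the fitted response surface to the
degradation level you want.

The package ships the worked case study on which it was developed: acid and
alkali degradation of chlorthalidone, a thiazide-like diuretic, with HCl/NaOH
strength 0.01–0.1 mol/L, temperature 55–80 °C, and time 30–60 min (acid) or
15–30 min (alkali).  The `chlorthalidone_*()` accessors return those inputs.

## The model

For k two-level factors, actual settings are mapped to coded units,
$x = (\text{actual} - \text{midpoint})/(\text{half-range})$, so the low and
high levels sit at −1 and +1.  The response is modelled by the saturated
multilinear polynomial; for k = 3:

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_3
      + \beta_{12} X_1 X_2 + \beta_{23} X_2 X_3 + \beta_{13} X_1 X_3
      + \beta_{123} X_1 X_2 X_3 .$$

Because the coded effect columns of a full factorial are mutually orthogonal,
the least-squares coefficients have closed forms,
$\beta_0 = \sum Y / 2^k$ and $\beta_j = \sum X_j Y / 2^k$, and the model
interpolates all $2^k$ observations exactly (`fd_fit()`; the equivalence with
`lm()` is asserted in the test suite against a normal-equations oracle).

```{r fit}
des <- fd_design(chlorthalidone_factors("acid"))
resp <- assemble_responses(chlorthalidone_runs("acid"), des, label = "acid")
mod <- fd_fit(des, resp, label = "acid")
model_equation(mod)
```

## Effect screening

`yates_analysis()` applies the Yates algorithm — k passes of pairwise
sums/differences over the standard-order response vector — giving every
factorial contrast in one sweep.  Each effect is contrast$/2^{k-1}$ (twice
the regression coefficient), its mean square contrast$^2/2^k$ on 1 df.

An unreplicated factorial has no residual degrees of freedom, so the error
mean square is *pooled* from the `pool_size` smallest effect mean squares
(default 2, hence error df = 2 and a 1%-level critical value
$F(1,2;0.01) \approx 98.5$).  This is a deliberately aggressive screen: with
only 2 df in the denominator, the critical value is large and only dominant
effects clear it.

```{r screen}
yt <- yates_analysis(resp, rounding = "integer", f_critical = 98.49)
f_screen(yt)
f_screen(yt, main_effects_only = TRUE)
```

Two judgment calls deserve explanation:

* **Integer rounding.** Hand-worked Yates tables in the method-development
  literature round responses to integers before the transform;
  `rounding = "integer"` (half away from zero) reproduces that arithmetic,
  while the default `"none"` keeps full precision for new analyses.  One
  packaged alkali response (32.51) was rounded *down* to 32 in the original
  worked table; to reproduce that table verbatim, pass its printed integer
  vector rather than re-rounding the raw responses.
* **Interactions in the screen.** In the acid data the temperature × time
  interaction clears the same F threshold (F = 200 > 98.49) as the two main
  effects.  Screening reports often discuss only factors;
  `main_effects_only = TRUE` reproduces that reading, but the default applies
  the threshold to every term, because ignoring a significant interaction is
  a judgment, not arithmetic.

The Pareto view normalizes each squared effect to a percentage of the total,
$100 E^2 / \sum E^2$ (`pareto_squares()`, plotted with `autoplot()`).  The
default ranking is by *signed* effect value, matching the tabulated
convention this workflow comes from; `sort = "abs"` gives the conventional
magnitude ranking.

The explained share of a reduced model is
`reduced_r_squared()` $= \sum \mathrm{MS}_{\text{kept}} / \sum \mathrm{MS}_{\text{all}}$;
the kept set is always an explicit argument, never inferred, because the
screening rule and the published reduced model need not agree (in the alkali
case study the screen keeps only temperature, while the reported R² of
0.9770 arithmetically includes the heating-time mean square as well).

## Surface inversion and decoding

With all factors but one fixed, the multilinear polynomial is linear in the
remaining factor, so the coded level attaining a target response is solved
in closed form (`invert_single_factor()`), tabulated over a grid
(`surface_table()`), and decoded back to actual units
(`decode_values()`).  Published surface tables are computed from the 2-dp
rounded equation; `rounding = "2dp"` reproduces that arithmetic exactly,
while the default uses full precision.  Solutions outside the coded
[−1, +1] domain are reported and flagged rather than clipped — they mark
unattainable targets, and the package warns on any decode outside the
domain because a two-level design supports no conclusions there.

```{r surface}
surface_table(mod, solve = "X3", grid_factor = "X2",
              grid_levels = c(-1, 0, 1), targets = c(10, 15),
              rounding = "2dp")
```

`choose_condition()` automates the final step: non-significant factors are
held at the midpoint (coded 0), the remaining factors except one are tried
at {−1, 0, +1}, and the last is solved exactly.  Among feasible points the
smallest max-|coded| wins, ties broken lexicographically — a deterministic,
documented rule.  Achievability is pre-checked by corner enumeration (a
multilinear function attains its extrema at corners), and an unattainable
target errors with the achievable range.

```{r optimum}
mod <- set_significant_terms(mod, yt, c("X2", "X3"))
choose_condition(mod, target = 10, rounding = "2dp")
```

For the acid system this lands at the acid-strength midpoint (0.055 mol/L),
the low temperature (55 °C), and a heating time just inside the high level —
i.e. heat with 0.055 M HCl at 55 °C for ~60 min for 10% degradation.  (Note
when comparing with the published narrative: the original text prints
"0.55 M" for the coded midpoint of 0.01–0.1 M, which decodes to 0.055 M; and
its alkali coded optimum −0.86 → 56.75 °C is not recoverable from its own
equation, which gives (10 − 19.64)/10.88 = −0.886 → 56.4 °C.  Both
arithmetic paths are available here; neither printed value is silently
"corrected".)

## Validation statistics

`method_validation`-style statistics accompany the optimization:

* `fit_calibration()` — least-squares line with a linearity F test.  The
  ANOVA is computed on per-concentration mean responses by default (df
  (1, m − 2) for m concentrations, matching the 5% critical value ≈ 7.7 for
  six levels), with a raw-replicate mode available.
* `coefficient_t_tests()` — slope/intercept t tests with *explicit* null
  values; an exact fit (zero residual variance) is flagged rather than
  producing an undefined t.
* `detection_limits()` — ICH DL = 3.3σ/S, QL = 10σ/S; σ defaults to the
  calibration residual SD.
* `precision_anova()` — balanced one-way ANOVA with day as the group:
  F = BMS/WMS against F(days − 1, days·(reps − 1)).
* `recovery_regression()` and `assay_content()` for accuracy and assay.

```{r precision}
prec <- chlorthalidone_precision()
prec |>
  filter(level == "80%") |>
  transmute(day, value = found_mg) |>
  precision_anova()
```

## Synthetic data and what the tests show

The generators in `sim_factorial_responses()`, `sim_calibration_data()` and
`sim_precision_table()` produce data with exactly the structure the analysis
assumes: a known coded-unit polynomial plus i.i.d. Gaussian response noise; a
straight calibration line with additive noise; and day-nested measurements
with independent between-day and within-day Gaussian components.  Each takes
an explicit seed through an isolated RNG stream, so results are reproducible
and the caller's RNG state is untouched.

Default simulation magnitudes mirror the case study (intercept ≈ 18%,
dominant effect ≈ 10%, response noise 0.5%; calibration 2–12 µg/mL in
triplicate), so documented examples and power studies live on the scale of
real stress data.  Problem sizes used in the shipped tests — 500 replicates
for bias checks, 2000 for the ANOVA type-I-error rate, k ≤ 5 for
design-level property tests — were chosen to keep Monte-Carlo error well
below the tolerances asserted while running in seconds.

What passing tests do *not* show about real data: real degradation responses
are not exactly multilinear in the factors (curvature needs centre points, a
stated non-goal), detector noise is rarely homoscedastic across a 6-fold
concentration range, and day effects can drift rather than scatter.  The
generators validate the *statistics*, not chromatography.

## Numerical choices

* Sums of squares that are zero in exact arithmetic (degenerate ANOVA cells,
  perfect calibration lines) are clamped to zero below the double-precision
  noise floor of the data's scale, so exact fits report `Inf` F values and
  `exact_fit`/`degenerate` flags instead of astronomically large noise
  ratios.
* The inversion refuses to divide by an effective linear coefficient below
  1e−12 (`degopt_no_solution`).
* Solved surface points are substituted back into the same coefficient set
  that produced them and must reproduce the target to 1e−6; this is asserted
  at construction, not left to the user.
* Ties among pooled mean squares are broken by stable ordering (first term
  in standard order wins), making pooling deterministic.
* Coefficients are stored at full precision everywhere; 2-dp values appear
  only where the published-arithmetic mode (`rounding = "2dp"`) or report
  formatting asks for them.

## Limitations

Only full 2^k designs are supported (no fractions, centre points, blocking,
or second-order designs); the pooled-error screen is sensitive to the
pooling choice when several mean squares are comparable; and the optimizer
explores single-factor solves over bound/midpoint combinations, which is
exhaustive for the designs this workflow targets but is not a general
constrained optimizer.
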