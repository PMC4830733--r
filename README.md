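# degopt

Design-of-experiments tools for optimizing forced-degradation (stress)
conditions during stability-indicating method development, with the
accompanying ICH Q2 validation statistics.

Forced degradation exposes a drug to acid, alkali, heat, oxidant or light to
generate its degradation products; a stability-indicating assay must then
quantify the intact drug free of interference.  The practical question is
which stress settings produce a *useful* amount of degradation (say 10%).
`degopt` answers it with a two-level full factorial workflow:

1. **Design** — the 2^k coded run matrix in standard (Yates) order, with all
   interaction columns (`fd_design()`), and coded ↔ actual conversion
   (`code_values()` / `decode_values()`).
2. **Response** — % degradation = 100 · (A_unstressed − A_stressed) /
   A_unstressed from peak areas (`percent_degradation()`,
   `assemble_responses()`).
3. **Screening** — the Yates algorithm for all factorial contrasts; effects
   E = contrast/2^(k−1), mean squares contrast²/2^k, pooled-error F tests
   (`yates_analysis()`, `f_screen()`), and a Pareto ranking of normalized
   squares 100·E²/ΣE² (`pareto_squares()`).
4. **Model** — the saturated coded-unit polynomial
   Y = β₀ + Σ βⱼXⱼ + Σ βᵢⱼXᵢXⱼ + β₁₂₃X₁X₂X₃ fitted by the orthogonal contrast
   formulas βⱼ = ΣXⱼY/2^k (`fd_fit()`), with a reduced-model R² from the
   mean-square shares (`reduced_r_squared()`).
5. **Optimization** — closed-form inversion of the fitted surface for one
   factor at a target % degradation (`invert_single_factor()`,
   `surface_table()`), selection of an in-domain optimum and decoding back to
   actual units (`choose_condition()`), and comparison with confirmation runs
   (`compare_predicted_observed()`).
6. **Validation** — calibration regression with linearity ANOVA and
   coefficient t tests, ICH detection/quantitation limits (3.3σ/S, 10σ/S),
   recovery regression, assay content, and day-grouped one-way ANOVA for
   intermediate precision (`fit_calibration()`, `detection_limits()`,
   `precision_anova()`, ...).

Synthetic-data generators with known ground truth
(`sim_factorial_responses()` and friends) support end-to-end identity tests
and power studies (`screening_power_report()`).  Results are tibbles, chain
with the pipe, and have `tidy()`/`glance()`/`autoplot()` methods.

The package ships the chlorthalidone case study it was built around
(acid/alkali stress factorials and a 3-day precision table) as plain CSV,
via `chlorthalidone_factors()`, `chlorthalidone_runs()` and
`chlorthalidone_precision()`.

## Worked example

```r
library(degopt)

des  <- fd_design(chlorthalidone_factors("acid"))
resp <- assemble_responses(chlorthalidone_runs("acid"), des, label = "acid")

yt  <- yates_analysis(resp, rounding = "integer", f_critical = 98.49)
f_screen(yt, main_effects_only = TRUE)
#> [1] "X2" "X3"

mod <- fd_fit(des, resp, label = "acid") |>
  set_significant_terms(yt, c("X2", "X3"))
model_equation(mod)
#> Y = 18.32 - 0.67 X1 + 10.26 X2 - 0.16 X1X2 + 4.56 X3 + 0.44 X1X3 + 2.59 X2X3 - 0.10 X1X2X3
mod$r_squared_reduced
#> 0.9462

choose_condition(mod, target = 10, rounding = "2dp")
#> <fd_condition> target 10% degradation (predicted 10%)
#>         factor   coded  actual units
#>  acid_strength  0.0000  0.0550 mol/L
#>    temperature -1.0000 55.0000  degC
#>           time  0.9848 59.7716   min
```

Reading the output: temperature (X2) and heating time (X3) dominate acid
degradation (their pooled-error F values exceed the 1% critical value 98.49)
and together carry 94.6% of the effect variation.  Solving the fitted
surface for 10% degradation, with the acid strength at its coded midpoint and
temperature at its low level, puts the heating time at coded 0.98 — i.e.
stress with 0.055 M HCl at 55 °C for ~60 min.  `run_degradation_analysis()`
performs the same steps in one call and `write_report()` serialises the
result (CSV tables + full-precision JSON).

## Scope

Full 2^k factorials only: no fractional designs, centre points, blocking or
response-surface (CCD/Box–Behnken) designs, and no chromatographic signal
processing (peak integration, retention matching) — the workflow starts from
peak areas or % degradation values.
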