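# ejectkin

Population kinetics of bacteriophage lambda DNA ejection, from calorimetric
and scattering time series.

When phage lambda meets its *E. coli* receptor LamB, the pressurized
intracapsid genome is ejected. Whether the ejections from a phage
population start all at once (synchronized, finishing within the ~10 s it
takes one genome to translocate) or straggle over minutes (desynchronized,
with stochastic initiation delays) is set by the mechanical state of the
packaged DNA — fluid-like above, solid-like below a transition temperature
`T*` that depends on Mg2+ concentration. `ejectkin` is for biophysicists
analysing this population kinetics from three kinds of instrument records:

* **ITC heat-flow curves** — each exothermic differential-power (DP) peak
  is modelled as an exponentially modified Gaussian (EMG)

  ```
  f(t) = a/(2b) * exp(c^2/(2b^2) + (d-t)/b) * [erf((t-d)/(c*sqrt(2)) - c/(sqrt(2)*b)) + 1]
  ```

  with area `a`, exponential damping `b`, width `c` and position `d`;
  component medians follow Pearson's second skewness law,
  `median = (d + b) - sqrt(c^2+b^2) * gamma / 3` with
  `gamma = 2 b^3 / (c^2+b^2)^(3/2)`. `fit_dp_curve()` deconvolves a DP
  curve into one or two EMG populations and `population_metrics()` reports
  median ejection times, the fast-population area fraction, and
  per-population baseline-return times.
* **Ejection enthalpy vs temperature** — `fit_two_segment()` detects `T*`
  as the slope-inversion breakpoint of `dH_ej(T)` (two independent
  weighted lines, exhaustive 0.1 °C grid search), `tstar_vs_mg()` maps it
  against MgCl2.
* **Time-resolved SAXS** — `construct_background()` (non-negative least
  squares over component profiles), `fit_dna_peak()` (Gaussian + line over
  q in [0.18, 0.32] 1/A), `ejection_rates()` (ln-area slopes split at
  20 s into synchronized/desynchronized regimes) and `arrhenius_fit()`
  (`ln k` vs `1/T`, activation energy `Ea = -slope * kB`).
* **Light scattering** — `normalize_intensity()`, `differentiate_decay()`
  and `scale_to_itc()` turn an intensity decay into an event-rate overlay
  in heat-flow units for cross-method comparison.

A per-virion stochastic generator (`simulation_config()`,
`simulate_ejection_times()`, `synthesize_dp_trace()`,
`synthesize_ls_trace()`, `synthesize_saxs_series()`,
`synthesize_enthalpy_series()`) renders all observables from one set of
ground-truthed ejection events — Bernoulli fluid/solid states, uniform
start jitter for the fluid population, exponential (optionally Arrhenius-
rated) initiation delays for the solid one, Beta-profile heat pulses, a
3.5 s exponential instrument response, and Gaussian noise — so every
analysis stage is testable without instrument files. See the methods
vignette (`vignettes/ejection-kinetics.Rmd`) for the model, the parameter
choices and their rationale, and known limitations.

## Worked example

Simulate the default 22 °C / 10 mM MgCl2 titration (below `T*`, so two
populations coexist), deconvolve it, and read off the population metrics:

```r
library(ejectkin)

cfg <- simulation_config(temperature_C = 22, mg_mM = 10, seed = 1)
events <- simulate_ejection_times(cfg)
trace <- synthesize_dp_trace(events)
fit <- fit_dp_curve(trace)
fit
#> <dp_fit> bimodal EMG fit, residual rms 0.000103 ucal/s
#> # A tibble: 2 x 9
#>   component      a     b     c     d mean_s  sd_s skewness median_s
#>       <int>  <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>    <dbl>    <dbl>
#> 1         1 0.0599  3.56  1.40  7.00   10.6  3.83     1.61     8.50
#> 2         2 0.587  54.4   1.10  8.28   62.7 54.4      2.00    26.4

population_metrics(fit)
#>   median_fast_s median_fast_se_s median_slow_s median_slow_se_s fraction_fast
#> 1           8.5              1.4         26.43              1.1          0.09
#>   equilibration_fast_s equilibration_slow_s
#> 1                22.62               218.12
```

The fit resolves a synchronized population (median ejection time ~9 s,
returning to baseline after ~23 s) carrying ~9% of the released heat, and
a desynchronized population (median ~26 s, baseline return ~218 s) — the
two-peak phenomenology of a below-transition titration. The transition
temperature itself comes from the enthalpy-versus-temperature breakpoint,
and the activation energy from the SAXS peak-area decays:

```r
fit_two_segment(synthesize_enthalpy_series(seq(22, 42, 2), mg_mM = 10))
#> <transition_fit> T* = 33.0 C (slope inversion, significant)

run_saxs_scenario(seed = 1)$arrhenius
#> <arrhenius_fit> Ea = 1.21e-19 J/virion (29.5 kT at 25 C), ln A = 24.87
```

`run_scenario(seed = 1)` runs every default condition end to end (ITC
deconvolution at six temperature/Mg conditions, the `T*` scan over 5-50 mM
MgCl2, the SAXS Arrhenius arm and the LS comparison) and prints a landmark
table with pass/fail flags against the scenario's calibration targets;
with `out_dir` set it also writes the per-stage CSV tables and a JSON
report.

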