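# optoshuttle

Quantifying nucleocytoplasmic shuttling kinetics from optogenetic
release, FRAP and FLIP experiments.

## The problem

How fast does a protein enter and leave the nucleus? `optoshuttle`
implements the analysis stack for an optogenetic assay that answers this
per cell: the protein of interest is fused to the Zdk peptide, which binds
a LOV domain anchored on the outer mitochondrial membrane (TOM20–LOV) in
the dark. Blue light dissociates the pair, releasing a pulse of protein
into the cytoplasm; in the dark it re-binds. Time-lapse imaging of the
mitochondrial, cytoplasmic and nuclear signals during release and recovery
constrains the six rate constants of a three-compartment model:

```
dM/dt = k_on C − k_off M
dC/dt = k_off M − k_on C + k_exp N − k_imp C
dN/dt = k_imp C − k_exp N
```

with `k_on`/`k_off` switching between lit and unlit values. The package is
aimed at cell biologists and image analysts running LOV/Zdk ("opto-release")
experiments, and provides:

* **kinetics** — exact simulation of the compartment model under arbitrary
  illumination schedules (`simulate_trace()`, `steady_state()`, `ode_rhs()`);
* **segmentation** — percentile-projection segmentation of multi-channel
  movies with interpolated per-seed thresholds and signal extraction
  (`segment_compartments()`, `extract_signals()`), plus regional analyses
  (`regional_gain_map()`, `average_pulse_response()`);
* **normalisation** — background subtraction and bilinear (per-phase
  linear) photobleaching correction (`bilinear_normalise()`);
* **fitting** — Levenberg–Marquardt fits with equal-compartment residual
  weighting, steady-state-constrained initial conditions, curvature-based
  confidence intervals, phase-restricted information analysis
  (`fit_opto_model()`, `phase_restricted_ci()`) and AIC/Akaike-weight
  model comparison (`compare_models_aic()`);
* **FRAP** — a reaction–diffusion simulator and fitter for cytoplasmic
  diffusivity and mitochondrial binding constants
  (`simulate_frap()`, `fit_frap()`, `bound_fraction()`);
* **FLIP** — a two-compartment loss-in-photobleaching model with
  double-exponential bleaching hazard (`simulate_flip()`, `fit_flip()`);
* **synthetic data** — a seeded movie generator with ground truth
  (`synthetic_movie()`), standing in for the microscope so every analysis
  path is testable offline.

Results are tibbles throughout; fits support `tidy()`, `glance()`,
`coef()` and `autoplot()`.

## Worked example

Simulate the standard release/recovery protocol (5 dark, 150 lit, 150 dark
frames, 4 s apart) at the dark-state binding medians, fit the dual-rate
model, and read off the rates:

```r
library(optoshuttle)

rates <- rate_params(
  k_imp = 0.002, k_exp = 0.002,          # nuclear import/export, s^-1
  k_on_unlit = 0.027, k_off_unlit = 0.019,  # dark-state binding medians
  k_on_lit = 0.03, k_off_lit = 0.2       # lit state: fast release
)
trace <- simulate_trace(rates, default_protocols("opto-standard"),
                        noise = noise_spec(0.01), seed = 1)
fit <- fit_opto_model(trace)
tidy(fit)
#> # A tibble: 7 × 5
#>   term        estimate std_error conf_low conf_high
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl>
#> 1 k_imp        0.00199 0.0000160  0.00196   0.00202
#> 2 k_exp        0.00199 0.0000163  0.00196   0.00202
#> 3 k_on_unlit   0.0270  0.000922   0.0251    0.0288
#> 4 k_off_unlit  0.0189  0.000684   0.0176    0.0203
#> 5 k_on_lit     0.0296  0.00190    0.0258    0.0333
#> 6 k_off_lit    0.196   0.0120     0.173     0.220
#> 7 M0           0.417   0.00203    0.413     0.421
```

At 1% observation noise every generating rate is recovered within its
interval: the dark-state binding constants to three decimals
(0.0270 / 0.0189 vs 0.027 / 0.019 s⁻¹), and `M0` sits at the dark
steady-state mitochondrial proportion (0.415). `glance(fit)` adds the
residual sum, AIC and convergence flag; `autoplot(fit)` overlays the
fitted curves on the data per compartment.

The same rates fall out of a rendered movie via the full pipeline:

```r
movie <- synthetic_movie(rates, spec = synthetic_cell_spec(size = 96, seed = 1))
masks <- segment_compartments(movie$stack, window_profile(n_seeds = 2))
raw   <- extract_signals(movie$stack, masks, movie$schedule)
fit2  <- fit_opto_model(bilinear_normalise(raw))
```

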