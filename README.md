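# fcspipe

A tidyverse-native R pipeline for **confocal fluorescence correlation
spectroscopy (FCS)** of fluorescently tagged proteins in cells and live
embryos — built for studies that ask whether a protein moves as a free
monomer, as an oligomer bound in slow complexes, or by active transport.

FCS records the intensity fluctuations of fluorophores crossing a
femtoliter-scale confocal volume and infers dynamics from the normalized
autocorrelation function (ACF)

    G(tau) = <I(t) I(t+tau)> / <I>^2 .

For free 3D diffusion through a Gaussian observation volume (radial waist
w0, structure factor K = z0/w0) one species contributes

    G(tau) = (1/N) (1 + tau/tau_D)^-1 (1 + tau/(K^2 tau_D))^-1/2 + G_inf ,

with particle number N, dwell time tau_D = w0^2/(4D), and long-lag
convergence G_inf ≈ 1. fcspipe implements this model plus its two-component
mixture (amplitude fraction F2 of a slow component), an optional
photophysical (triplet) prefactor `1 + (F_trip/(1+F_trip)) exp(-tau/tau_trip)`,
and a diffusion-plus-flow model with flow time tau_f (velocity v = w0/tau_f).
Around the models it provides every stage needed to run and validate a
complete study on synthetic ground truth:

* **Simulation** — Brownian-dynamics photon traces in a periodic box
  (mixtures, telegraph blinking, directed flow, rare bright aggregates),
  reproducible from a seed (`simulate_trace()`, `make_regime_catalog()`).
* **Correlation** — a multi-tau software correlator with symmetric
  normalization and segment-wise uncertainties, validated against an exact
  direct-sum reference (`autocorrelate()`, `correlate_direct()`), plus
  intensity-spike screening for aggregates (`detect_spikes()`).
* **Fitting & selection** — bounded weighted Levenberg–Marquardt fits,
  dye-based volume calibration, and nested-model F-tests (on a thinned,
  approximately independent lag subset) with BIC arbitration to decide
  one- vs two-component diffusion and diffusion vs directed transport
  (`fit_acf()`, `select_model()`, `calibrate_volume()`).
* **Cohort statistics** — per-measurement tables with QC labels, group
  mean/SD/SEM summaries, pooled-variance Student's t-tests, and
  intensity-vs-N brightness regressions whose slope ratio exposes
  oligomerization (`fit_records()`, `summarize_groups()`,
  `brightness_regression()`, `compare_conditions()`).

All user-facing functions take a data frame first and return tibbles;
fitted objects support `tidy()`/`glance()` and `autoplot()`.

## Worked example

Simulate a 10-s acquisition of a mixture — 60% fast monomer
(D = 19 µm²/s) and 40% slow complex (D = 0.9 µm²/s) — then correlate,
choose between one- and two-component diffusion, and read off the
physical quantities:

```r
library(fcspipe)

vol <- observation_volume(w0 = 0.25, z0 = 1.25)   # calibrated beam geometry

cfg <- sim_config(vol = vol, duration = 10, seed = 42)
n_box <- prod(2 * cfg$box) / vol$V_eff            # molecules per unit N
mix <- rbind(
  species_spec(D = 19,  brightness = 8000, mean_count = 0.6 * n_box,
               label = "monomer"),
  species_spec(D = 0.9, brightness = 8000, mean_count = 0.4 * n_box,
               label = "complex"))
trace <- simulate_trace(mix, cfg)
curve <- autocorrelate(trace)

sel <- select_model(curve, list("D1P", "D2P"))
sel$case
#> [1] "Case 2"
tidy(sel)
#> # A tibble: 2 × 7
#>   model_id converged n_free   rss chi2_red   bic chosen
#>   <chr>    <lgl>      <int> <dbl>    <dbl> <dbl> <lgl>
#> 1 D1P      TRUE           3 191.     1.69   72.4 FALSE
#> 2 D2P      TRUE           5  83.5    0.752 -14.4 TRUE

fit <- sel$fits[[sel$chosen]]
fit
#> ACF fit: D2P model, 116 points from lag 0.01 ms, converged
#>   N         1.3209 (se 0.021)
#>   tau_D1    0.81794 ms (se 0.167 ms)
#>   tau_D2    15.324 ms (se 3.3 ms)
#>   F2        0.38646 (se 0.054)
#>   G_inf     0.98581 (se 0.00286)
#>   chi2_red  0.7519 on 116 points

derived_quantities(fit, vol, background = cfg$background_rate) |>
  dplyr::select(model_id, N, D1, D2, F2, cpm)
#> # A tibble: 1 × 6
#>   model_id     N    D1    D2    F2   cpm
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 D2P      0.934  19.1  1.02 0.386 2832.
```

The selection correctly calls the measurement two-component ("Case 2");
the recovered diffusion coefficients (19.1 and 1.02 µm²/s), slow-component
amplitude fraction (0.39 vs the simulated 0.4) and background-corrected
particle number (0.93 vs the configured 1.0) match the ground truth. `cpm`
is the molecular brightness (counts per second per particle); comparing it
— or the slope of mean intensity against N across measurements
(`brightness_regression()`) — between constructs is the oligomerization
readout: a particle carrying four fluorophores shows a four-fold slope.

`run_pipeline(run_config(...))` chains simulation, correlation, fitting,
selection, QC and the cohort report, writing tab-separated fit tables,
group summaries, pairwise tests and a run log; the same configuration and
seed always reproduce byte-identical outputs.

See the methods vignette (`vignettes/fcs-methods.Rmd`) for the model
definitions, parameter conventions, simulator assumptions and the
numerical choices behind fitting and model selection.

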