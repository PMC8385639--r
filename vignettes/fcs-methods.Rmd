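---
title: "Models and methods behind fcspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fcspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fcspipe implements the complete computational chain of a confocal
fluorescence correlation spectroscopy (FCS) study of protein dynamics in
living cells and embryos: trace simulation with known ground truth,
multi-tau autocorrelation, model fitting with selection between competing
transport models, and cohort-level statistics. This vignette explains the
models, the tunable parameters, and the numerical and design choices, in
enough detail that a user can judge what a passing test suite does — and
does not — establish about real data.

## The autocorrelation models

FCS infers dynamics from the normalized autocorrelation function (ACF) of
the detected intensity,
$G(\tau) = \langle I(t)\, I(t+\tau)\rangle / \langle I \rangle^2$.
For free 3D diffusion through a Gaussian observation volume with radial
waist $w_0$ and structure factor $K = z_0/w_0$, one species contributes the
decay factor

$$ g_D(\tau;\tau_D) = \left(1+\frac{\tau}{\tau_D}\right)^{-1}
   \left(1+\frac{\tau}{K^2\tau_D}\right)^{-1/2}, $$

and the one-component model is $G(\tau) = \frac{1}{N} g_D(\tau;\tau_{D1}) +
G_\infty$ (`acf_d1p()`). The fitted symbols are:

* $N$ — mean number of particles in the effective volume
  $V_{\mathrm{eff}} = \pi^{3/2} w_0^2 z_0$; the ACF amplitude is $1/N$.
* $\tau_{D}$ — dwell time of a species, related to its diffusion
  coefficient by $\tau_D = w_0^2/(4D)$ (`tau_to_diffusion()`).
* $F_2$ — amplitude fraction of the second, slower component in the
  two-component model (`acf_d2p()`), which is the amplitude-weighted sum of
  two decay factors. $F_2$ is *not* a mole fraction unless both species are
  equally bright — a particle contributes with the square of its
  brightness — so every result table carries an `F2_caveat` flag and $F_2$
  should be read as reporting on changes in either fraction or brightness.
* $F_{\mathrm{trip}}, \tau_{\mathrm{trip}}$ — photophysical (triplet-like)
  relaxation, entering as the prefactor
  $1 + \frac{F_{\mathrm{trip}}}{1+F_{\mathrm{trip}}}
  e^{-\tau/\tau_{\mathrm{trip}}}$ (`acf_d1p_triplet()`). The
  $F/(1+F)$ form is used exactly as the instrument software conventions
  this package mirrors; note that many textbooks use $F/(1-F)$, so values
  are not interchangeable between conventions.
* $\tau_f$ — flow lag time of the diffusion-plus-flow model
  (`acf_flow_diffusion()`), which multiplies $g_D$ by
  $\exp[-(\tau/\tau_f)^2/(1+\tau/\tau_{D1})]$; the flow velocity is
  $v = w_0/\tau_f$. A pure-flow model (`acf_flow()`,
  $\frac{1}{N}e^{-(\tau/\tau_f)^2} + G_\infty$) is included as a selection
  competitor because rejecting it is part of demonstrating that a signal is
  genuinely diffusive-plus-directed rather than purely directed.
* $G_\infty$ — long-lag convergence value, expected to be 1 for a
  normalized, stationary measurement. It is fitted rather than fixed, and a
  fit whose $|G_\infty - 1| > 3\%$ raises a warning, since larger drifts
  indicate bleaching, instability, or an unconverged measurement.
* $K$ — fixed during ordinary fits to the calibrated value (default 5);
  freed only in `calibrate_volume()`, which fits a reference dye of known
  $D$ (conventionally 400 µm²/s) and returns
  $w_0 = \sqrt{4 D_{\mathrm{ref}} \tau_D}$, $z_0 = K w_0$.

Component 1 is by convention the *fast* component
($\tau_{D1} \le \tau_{D2}$); fits that converge with swapped labels are
reordered, exchanging $F_2 \leftrightarrow 1-F_2$. All internal units are
seconds and micrometers; lag times appear in milliseconds only in printed
output.

The root-mean-square displacement helper uses the one-dimensional
convention $\sqrt{2Dt}$. For D = 30 µm²/s this gives 7.75 µm in one second
— the scale that makes passive diffusion a plausible mechanism for
populating a motor axon — and 1.41 µm for D = 1 µm²/s. The alternative 3D
convention $\sqrt{6Dt}$ would give 13.4 and 2.4 µm; the 1D convention is
adopted because it reproduces the first of these published scales exactly.

## The correlator

`autocorrelate()` emulates a hardware multi-tau correlator: `m = 16`
linearly spaced lag channels at the base bin width, then `m/2` channels per
block with the trace coarsened two-fold (adjacent-bin averaging) between
blocks. The resulting quasi-logarithmic grid spans from one bin width
(default 10 µs) up to one tenth of the acquisition; longer lags have too few
independent samples to be stable and are dropped. Normalization is
symmetric — each lag divides by the product of the head and tail means —
which makes $G \to 1$ for uncorrelated stationary signals and suppresses
first-order bias from slow drift or bleaching. The estimator is validated
against `correlate_direct()`, an exact $O(NL)$ direct sum with the same
normalization, to $10^{-10}$ on all shared base-resolution lags.

Per-lag uncertainties are the standard error across five equal trace
segments correlated independently. These feed weighted fits
($w_i = 1/\mathrm{se}_i^2$) and are the honest caveat of this design:
segment estimates at a given lag are correlated, so the absolute scale of
the uncertainties is approximate (reduced chi-square values around 1–3 on
well-behaved simulations), while relative weighting across lags is sound.

Spike screening (`detect_spikes()`) flags bins exceeding the median plus
`k = 5` robust standard deviations (MAD, with a Poisson floor
$\sqrt{\mathrm{median}}$ when the MAD degenerates) on a millisecond-rebinned
trace. Bright slow aggregates transiting the volume produce such spikes;
flagged measurements are excluded from cohort statistics but retained with
a QC label, mirroring the field practice of avoiding visible aggregates
during acquisition.

## The simulator

`simulate_trace()` is a Brownian-dynamics photon simulator: molecules take
per-axis Gaussian steps of SD $\sqrt{2D\,dt}$ (plus uniform drift for flow)
in a periodic box, emit at rate
$B \exp[-2(x^2+y^2)/w_0^2 - 2z^2/z_0^2]$, and each bin's count is a Poisson
draw of the summed rate plus background. This is the minimal generative
model exactly consistent with the assumptions behind the closed-form ACFs:
3D Gaussian detection, free diffusion, uniform flow, Markovian blinking.

Numerical choices, each visible as a `sim_config()` parameter:

* **Integration step** `dt = 1e-5` s doubles as the photon bin width, so
  the shortest correlator lag is 10 µs. It satisfies
  $dt \le w_0^2/(20 D_{\max})$ (positions decorrelate by at most ~5% of the
  waist per step) for every default regime; blinking species additionally
  require $dt \le \tau_{\mathrm{trip}}/5$. Both constraints are enforced
  with explicit configuration errors.
* **Box size.** A periodic box truncates the long-wavelength relaxation
  modes of the concentration field, which steepens the simulated ACF
  relative to the infinite-medium model. Evaluating the exact mode-sum ACF
  for a periodic box shows the fitted diffusion time is biased by −8% with
  half-lengths $3\times(w_0,w_0,z_0)$, −2% at $5\times$ and about −0.5% at
  $8\times$, which is the default. The −2% residual at $5\times$ matters:
  it is large enough for model selection to absorb it into a spurious flow
  term on long, well-sampled traces. Molecules far outside the detection
  region advance by exact aggregated multi-step jumps (a 5σ excursion bound
  keeps them provably outside an $e^{-16}$ emission surface), which makes
  the larger box cost only ~25% more wall time than the small one.
* **Blinking** is a two-state telegraph process with stationary dark
  fraction $f$ and relaxation time $\tau$; it multiplies the ACF by
  $1 + \frac{f}{1-f}e^{-\tau/\tau_{\mathrm{rel}}}$, so fitted photophysics
  satisfies $F_{\mathrm{trip}}/(1+F_{\mathrm{trip}}) = f/(1-f)$.
* **Background** (default 500 counts/s) is uncorrelated and dilutes the ACF
  amplitude by the squared signal fraction; `derived_quantities()` applies
  the standard correction $N = N_{\mathrm{app}}\,((F-B)/F)^2$ when the
  background rate is known, and computes counts-per-molecule from the
  background-subtracted intensity.

`make_regime_catalog()` bundles the study conditions as labeled fixtures:
a free fluorescent protein at 30 µm²/s; a two-component mixture of a
19 µm²/s monomer and a 0.91 µm²/s complex with slow-amplitude fraction
drawn in [0.2, 0.6]; an oligomerization-deficient truncation (single fast
species, with a weak-intermediate variant at diffusion-time ratio 5–20); a
blood-flow positive control at 54.5 µm/s; and an aggregate regime
superposing rare 50-fold-brighter slow particles on the monomer background.
Default conditions chosen once where the study leaves them open: occupancy
$N \approx 1$ in the focal volume (FCS is designed for single-molecule
occupancy; fewer molecules also bound the simulation cost), monomer
brightness 8 kHz/molecule (a typical well-excited fluorescent protein,
within the 3–10 kHz range such experiments report), acquisitions of 30 s as
in the emulated measurements.

The simulator deliberately omits photobleaching, detector afterpulsing and
dead time, and refractive distortion of the focal volume in tissue. Passing
recovery tests therefore demonstrate the *analysis chain* is correct and
well-calibrated under the model's own assumptions; they do not certify
robustness to those instrument- and sample-dependent artifacts.

## Fitting and model selection

`fit_acf()` minimizes the weighted residual sum of squares with bounded
Levenberg–Marquardt (maximum 500 iterations, tolerance $10^{-10}$), with up
to five restarts from multiplicatively perturbed starting values if the
first attempt fails. Bounds: $N > 0$, all times positive, $0 \le F_2 \le 1$,
$F_{\mathrm{trip}} \ge 0$. Standard errors come from the covariance of the
linearized problem at the optimum. Starting values (`default_init()`) are
deterministic: plateau from the last decade of lags, $N$ from the first
fitted lag's amplitude, $\tau_{D1}$ at the half-amplitude lag,
$\tau_{D2} = 50\,\tau_{D1}$, $F_2 = 0.3$, and the photophysical time just
inside the observed window (a start below the first measured lag can strand
the triplet term in a local minimum). A curve that does not decay above its
plateau is reported as unfittable rather than fitted. Fit windows follow
the emulated study's conventions: lags from 0.001 ms for triplet models,
0.01 ms for diffusion-only and flow models.

`select_model()` compares candidates on a common window (the largest of
their fit-start conventions, so residuals are commensurable). Nested pairs
— one-component inside two-component, inside the triplet variants, inside
diffusion+flow; pure flow inside diffusion+flow — are compared by an
F-test at $\alpha = 0.05$ on the weighted RSS: the richer model survives
only when its improvement is significant. Among the survivors the
minimum-BIC model is chosen. This operationalizes the visual
residual-inspection practice of the emulated study as a reproducible rule;
the per-measurement outcome is labeled "Case 1" (one-component chosen) or
"Case 2" (two-component chosen).

One statistical subtlety deserves emphasis. Neighboring lag estimates of a
correlation curve are computed from largely the same photon pairs, so
their errors are strongly correlated; an F-test that counts every lag of a
multi-tau grid as an independent observation is grossly anticonservative —
on simulated pure-diffusion traces it "detects" a flow component in over a
third of measurements, with nominal p-values as small as $10^{-9}$, by
chasing coherent noise excursions that span many adjacent lags. The
nested-model tests are therefore evaluated on a thinned subset of the
residuals, one lag per octave, which is approximately the spacing at which
lag estimates decorrelate. On simulated ground truth this restores the
empirical false-selection rate to the nominal level while leaving the
power to detect genuine transport or second components — whose signatures
span many octaves — at 100%. The null-calibration property is still
asserted conservatively at twice the nominal level
($\le 2\alpha$ spurious selections).

Two species are resolvable in practice only when their diffusion times
differ by roughly a factor of 1.6 or more; the suite tests this as a trend
(selection rate at ratio 1.2 strictly below ratio 5 under matched noise),
not as a sharp threshold.

## Cohort statistics

`fit_records()` turns a catalog of traces into one tidy row per
measurement (QC flags, chosen model, case label, parameters, standard
errors, derived quantities). `summarize_groups()` reports mean, SD and SEM
per group — figures in this field put SD on error bars while text quotes
SEM, so both are emitted, labeled. Two-group comparisons use the classical
pooled-variance Student's t-test (`ttest_unpaired()`, matching the emulated
study's stated method; Welch is deliberately not substituted), with the
degenerate zero-variance-equal-means case returning $p = 1$ by convention.
No multiplicity correction is applied (none is applied in the emulated
analyses); raw p-values carry the usual star conventions.
`brightness_regression()` fits the mean intensity against fitted $N$ per
construct with a free intercept (background offsets exist in real traces):
the slope is the apparent molecular brightness, a 4× slope ratio is the
oligomerization signature, and slope differences get a z-test.

## Problem sizes used by the test suite

The automated suite exercises the full chain at desk scale, chosen to keep
the whole run in tens of minutes on one core while leaving comfortable
statistical margins: ten 30-s single-species acquisitions for the
convergence and recovery checks; twenty 10-s flow and twenty 8-s diffusion
acquisitions for transport discrimination; five concentrations per
construct at 15 s for the brightness slopes; twenty synthetic curves per
condition for selection-rate properties; shorter (2–24 s) acquisitions for
focused unit checks. Longer acquisitions only tighten the margins.

## Known limitations

* Per-lag uncertainties are approximate in absolute scale (segment
  correlation), so reduced chi-square is a relative, not absolute, fit
  quality measure.
* The F-test inherits the correlated-residual approximation above;
  selection rates are calibrated empirically in the suite rather than
  guaranteed by distribution theory.
* $F_2$ confounds mole fraction and brightness (flagged in every output);
  no brightness-squared correction is attempted because the species'
  brightnesses are unknown in the emulated setting.
* The simulator's omissions (bleaching, afterpulsing, tissue optics) are
  stated above; vendor time-tagged instrument files are out of scope — the
  documented plain-text layouts plus a conversion hook keep the pipeline
  testable end to end.
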