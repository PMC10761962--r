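---
title: "Modelling light-patterned cooperation on sucrose gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light-patterned cooperation on sucrose gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(optocoop)
```

## The system and the model

`optocoop` simulates a lawn of budding yeast embedded in a thin gel on top
of a sucrose reservoir, where expression of the periplasmic invertase
(Suc2p) is placed under optogenetic control. Illuminated cells behave as
*cooperators*: they produce invertase, hydrolyse sucrose in their
periplasm and release the resulting hexoses, which diffuse and can be
consumed by any cell. Cells kept in the dark behave as *cheaters*: they
produce (almost) no invertase but grow on the hexoses released by their
neighbours. Because the gel is thin (≈2.35 mm, cells in a 0.67 mm top
layer), vertical diffusion equilibrates much faster than horizontal
transport, and the model is restricted to the horizontal dimensions.
Stripe patterns are translationally symmetric along the stripe, so 1D is
the faithful reduction used throughout; 2D grids are supported for
raster-mask patterns.

Five fields evolve on the grid: sucrose $S$ and hexose $H$ (mol/L),
invertase $E$ (mol per litre of gel), cell density $N$ (CFU/mL, 1 CFU
treated as 1 cell), and the cumulative hexose uptake $U$ (a diagnostic).
With $N' = 10^3 N$ the density in cells per litre:

$$
\begin{aligned}
\partial_t S &= D_S \nabla^2 S - v, &
v &= k_{cat} E \frac{S}{K_S + S} + k_{spont} S\\
\partial_t H &= D_H \nabla^2 H + 2\,\varphi\, v - u, &
u &= N' \left( V_{hi}\frac{H}{K_{hi}+H} + V_{lo}\frac{H}{K_{lo}+H}\right)\\
\partial_t E &= \alpha(x)\, N' - \delta_E E, &
\partial_t N &= \mu_{max} \frac{H}{K_H + H}\, N,\qquad
\partial_t U = u + 2(1-\varphi)v
\end{aligned}
$$

One sucrose yields two hexoses; $\varphi$ (`phi_leak`, default 1) is the
fraction of the hydrolysis product that reaches the shared extracellular
pool, the remainder being captured directly by the producing cell (routed
straight into $U$). The identity $2\,\partial_t S + \partial_t H +
\partial_t U = 0$ holds pointwise for every parameter set and is the
package's running mass audit (`sugar_total()`).

Three modelling decisions deserve emphasis:

* **The enzyme field is immobile.** Invertase is retained in the
  periplasm and the cells are gel-trapped microcolonies, so $E$ has no
  diffusion term; with the default `delta_E = 0` it also does not decay,
  consistent with the enzyme's measured stability over the experiment
  durations.
* **Growth is Monod in hexose and not stoichiometrically tied to
  uptake.** The two terms are deliberately separate, mirroring the
  two-part structure of the original model (enzymatic/transport kinetics
  plus a Monod growth law). Conservation is therefore audited on sugars,
  not on biomass, and the growth plateau emerges from sucrose exhaustion
  rather than from a yield coefficient. `N_max` (default off) exists only
  as a guard against abusive parameter choices.
* **Light maps to a binary production rate.** $\alpha(x)$ equals
  `alpha_coop` where the local intensity exceeds 10% of the device
  maximum (1.13 mW/cm²) and the leaky-promoter rate `alpha_cheat`
  elsewhere. The underlying model is known not to capture the graded
  dose response at low intensity, so the reproduction targets all use
  effectively binary patterns; a Hill mapping (`alpha_map(...,
  "hill")`) is provided for exploration only. Patterns are static in
  time, as in the experiments.

## Parameters, units and provenance

Concentrations are mol/L, per-cell rates mol s⁻¹ cell⁻¹, diffusivities
µm²/s, growth rates 1/h, densities CFU/mL; internally lengths are mm and
time is hours, with all conversions concentrated in one audited layer
(`internal_units()`). Three parameters are fitted values reported for the
optogenetic strain and are labelled `paper` in the provenance attribute:

| parameter | value | meaning |
|---|---|---|
| `alpha_coop` | 1.8e-24 mol s⁻¹ cell⁻¹ | induced invertase production |
| `alpha_cheat` | 1.5e-25 mol s⁻¹ cell⁻¹ | leaky (dark) production |
| `mu_max` | 0.27 h⁻¹ | maximal specific growth rate |

The remaining constants are *literature placeholders* (labelled
`fallback`), chosen once from the quantitative sucrose-cooperation
literature because the original supplementary table was not available to
this implementation: `D_H` = 600 and `D_S` = 500 µm²/s (hexose/sucrose in
dilute gel), `K_S` = 26 mM, `K_hi` = 1 mM, `K_lo` = 20 mM, `K_H` =
0.1 mM, `k_cat` = 1000 s⁻¹ (order of magnitude for the invertase
turnover), `V_hi` = 1.1e-17 and `V_lo` = 2.7e-17 mol s⁻¹ cell⁻¹ (hexose
transport capacity per cell from dry-mass scaling). Initial conditions:
1% w/v sucrose = 10 g/L ÷ 342.30 g/mol = 29.2 mM, $H_0 = E_0 = 0$, and a
lawn at $N_0 = 10^6$ CFU/mL — a placeholder for the plated OD 0.1, which
is recorded in every config. Every run writes the fully resolved set with
units and provenance (`params_dump()`), and `kinetic_params()` validates
positivity, `phi_leak` ∈ [0,1] and `alpha_cheat` ≤ `alpha_coop`.

With this a-priori set, the package reproduces the headline observables
within their stated bands (see `scripts/acceptance.R`), so the optional
calibration pass over `D_S`/`D_H` foreseen for placeholder parameters was
not needed; the defaults have not been tuned against any target.

## Numerics

The method-of-lines system is stiff in two ways: diffusion at 0.1 mm
spacing (CFL-limited explicit steps of seconds) and, at high cell
density, hexose uptake (effective rate constants approaching 0.01 s⁻¹).
The integrator therefore uses Strang splitting:

1. half-step of diffusion for $S$ and $H$ by Crank–Nicolson, solved with
   sparse Cholesky factors cached per step size (3-point/5-point
   Laplacian; no-flux boundaries by mirror ghost cells, periodic by
   wraparound — both closures have exactly zero column sums, so the
   diffusion step conserves mass to solver round-off);
2. a full step of the local kinetics with an embedded Bogacki–Shampine
   RK23 pair and proportional step-size control (`rtol` relative to each
   field, `atol` relative to per-field reference scales — S/H/U share the
   concentration scale, E is floored at a fraction of its hourly
   production, N at 1 CFU/mL — so all-zero fields cannot collapse the
   error norm);
3. the second diffusion half-step.

Accepted step sizes live on a halving ladder under `max_dt` (default
0.05 h) so factorizations are reused; output times are hit exactly.
Rejected steps, step-size extrema and minimum field values are reported
in the trajectory diagnostics. Positivity is enforced by clipping to
zero after each accepted step; the Michaelis–Menten and Monod terms
vanish at zero so clipping is benign, and the clipped mass is accumulated
per field and must stay below 1e-8 of the sugar total (tested). The
well-mixed reference `run_0d()` integrates the same kinetics with an
independent adaptive Cash–Karp RK45, and a homogeneous spatial run must
match it to 1e-4 — a dual-route check that shares no stepping code.

Degenerate inputs are errors, not guesses: non-finite states abort the
run, a step-size underflow aborts with the time of failure, `alpha`
fields must match the grid, and `out_times` must lie inside the
integration window.

## Readouts

* `mean_density_curve()` averages $N$ over a region of interest;
  `max_growth_rate()` fits a smoothing spline (15 effective degrees of
  freedom, the plate-reader convention) to $\ln N$ versus time and takes
  the maximal derivative — invariant to rescaling $N$, so it works
  identically on calibrated and uncalibrated curves. `final_density()`
  requires a plateau (relative slope below 5% across the trailing
  window) and otherwise returns the end value with a warning.
* `cooperator_benefit()` is the density at the centre of an illuminated
  stripe minus the density at the centre of a dark stripe. Centres are
  computed **from the pattern metadata, never from the density field**,
  because the experimental regions of interest were defined by the
  projected pattern; the stripe nearest the domain centre is used, and a
  uniform pattern is a hard error rather than a silent zero.
* `cutoff_wavelengths()` reads the two bandpass cut-offs where
  $B(\lambda)$ crosses 70% of its maximum, by linear interpolation
  between sampled wavelengths (the curve is sampled, no functional form
  is claimed). Missing crossings are reported as undefined with a
  reason; non-unimodal sweeps trigger a warning. Sweeps evaluate at
  t = 40 h and the line-width profiles at t = 85 h, matching the
  corresponding experiments; sweep domains cover two wavelengths with
  periodic boundaries, the natural unit cell of an infinite stripe
  array.
* Stripe generators keep the duty cycle fixed (default 0.25, i.e. 75%
  dark) so mean illumination — and hence cooperator frequency — is
  constant across wavelengths. Patterns sample cell centres, which keeps
  α exactly two-valued; the duty-weighted mean-α identity is exact
  whenever the lit width is grid-commensurate and within one cell
  otherwise.

## The synthetic observation model

`synth_timelapse()` stands in for the plate-scanner timelapses: it runs
the simulator, maps density to gray levels through a monotone
log-saturating calibration `I_bg + a log10(1 + N/N_ref)` (16-bit by
default), applies Gaussian optical blur and additive read noise, and
quantizes — returning both the observed stack and the hidden truth.
`image_to_density()` inverts real-format frames: subtract the first
(pre-growth) frame as background, clamp, invert the calibration, flag
saturated or out-of-range pixels. The calibration shape and its
parameters are this module's own ground truth: the real instrument's
curve was not available, so correctness is defined as *closure*
(forward → inverse recovers the field within quantization and noise
bounds, and the analysis pipeline recovers the ground-truth benefit
within noise-propagated tolerances that shrink as the noise does), not
as matching a particular instrument. Seeds are mandatory wherever noise
is drawn and the caller's RNG state is restored. What the generator does
*not* emulate — condensation droplets, lid reflections, plate-edge
effects, colony-scale texture — bounds what a green pipeline test
establishes: recovery under the stated noise model, not robustness to
real-plate artefacts. `phenomenological_lawn()` provides closed-form
logistic lawns so the metrics layer can be unit-tested without PDE
solves.

## File formats

Configs are YAML with strict unknown-key rejection and an FNV-1a content
hash stamped into every output; parameter dumps are flat `key = value`
text. Raster masks load from grayscale PNG or plain-text PGM with a
sidecar scale file. Trajectories persist as one full-precision CSV per
stored time plus an index and a JSON metadata file (loss-free round
trip, tested); synthetic stacks persist as per-page PGM plus a CSV
index. TIFF was not used because no TIFF codec package is available in
the supported environment; the CSV/PGM forms are plain text and
diff-able, which suits provenance better.

## Known limitations

* The graded light-dose response is not modelled (binary α by default);
  absolute growth rates across light doses are out of scope.
* Glucose and fructose are treated as one hexose pool, as in the source
  model.
* `N_0` in CFU/mL and the scanner calibration are synthetic-world
  choices; absolute densities carry that uncertainty, which is why the
  benefit target is only claimed within a factor of two.
* 1D is exact only for translationally symmetric patterns; image masks
  run in 2D at correspondingly higher cost.
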