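---
title: "Coupled excitable networks: model, wave theory and quantification methods"
author: "stencen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled excitable networks: model, wave theory and quantification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Cortical waves on the basal membrane of motile cells are organised by two
coupled excitable systems: a slow **signal-transduction excitable network**
(STEN; the Ras/PIP3/PKB layer) that carries propagating waves, and a fast
**cytoskeletal excitable network** (CEN; the Rac/F-actin layer) that is
slaved to it and produces the sharp actin bands and short-lived puncta
seen with F-actin biosensors.

Each network is an activator--inhibitor pair with a cubic-shaped
activator nullcline:

$$
\frac{\partial F_S}{\partial t} =
  D_{F_s}\nabla^2 F_S - (a_{1s} + a_{2s} R_S)\,F_S
  + \frac{a_{3s} F_S^2}{a_{4s}^2 + F_S^2} + a_{5s} + U_N,
\qquad
\frac{\partial R_S}{\partial t} =
  D_{R_s}\nabla^2 R_S + \epsilon_s(-R_S + c_{1s} F_S)
$$

The CEN has the same structure without a noise term in the activator but
with the STEN input entering as an offset on its effective inhibition,
$-(a_{1c} + a_{2c}(R_C - s_{in}))F_C$, where
$s_{in} = s_c (R_S - R_0)$ and $R_0$ is the STEN's resting inhibition.
Raising $s_{in}$ lifts the CEN activator nullcline vertically and lowers
its firing threshold, slaving CEN firings to passing STEN waves.

Feedback from the cytoskeleton closes the loop through two linear
species driven by the CEN activator: a fast, local positive loop
$\dot Z_C = -p_1 Z_C + p_2 F_C$ and a slow, *global* negative loop
$\dot W_C = -p_3 W_C + p_4 F_C$.  Both act on the STEN through the
amplitude of its stochastic drive, $\sigma_N = u_b + Z_C - W_C$
(clamped below at zero -- a standard deviation cannot be negative, and
the clamp is what lets strong global inhibition silence triggering
altogether).  $U_N$ is zero-mean Gaussian white noise with standard
deviation $\sigma_N$; the CEN receives its own white-noise drive of
fixed amplitude $\sigma_c$ so that, even uncoupled, every site fires
occasionally.

# Default parameters and how they were chosen

All defaults live in one versioned configuration file,
`inst/extdata/default_params.cfg`, loaded by `modelParams()` and
editable through the flat `symbol = value` format of
`readModelConfig()`.  The constants are nondimensional (time and space
in simulation units); an optional calibration pair (seconds per time
unit, microns per grid step) can be attached to readouts as metadata.

The defaults were fixed once, by the following calibration procedure,
and are not tuned per experiment:

* **Excitable geometry.** `a1s=0.5, a2s=1, a3s=4, a4s=1, a5s=0.02,
  c1s=5` gives a unique rest state on the left branch of the cubic
  nullcline with threshold `th ~ 0.12` and a bistable window
  `[0.064, 1.52]` of clamped inhibition.  A 1.5x-threshold kick
  produces an excursion more than ten times the perturbation before
  returning to rest.
* **Slow inhibitor, finite range.** `eps_s = 0.05` with `d_fs = 0.5`
  and `d_rs = 1.0` makes the inhibitor's molecular dispersion
  $\sqrt{D_R/\epsilon_s} \approx 4.5$ exceed the activator's
  $\sqrt{D_F/a_{1s}} = 1$, so triggered waves travel at about 0.55 grid
  steps per time unit and stop after roughly 30 steps instead of
  sweeping the domain.
* **CEN eight-fold faster, spatially confined.** `eps_c = 0.4`
  (`eps_c/eps_s = 8` exactly) and small diffusion
  (`d_fc = d_rc = 0.05`) keep CEN firings brief and local; with the
  coupling off, the spatial autocorrelation length of CEN activity is
  under 3 grid steps (puncta, not waves).
* **CEN noise.** `sigma_c = 0.4` was calibrated so that, uncoupled,
  more than 90% of grid points fire at least once per 100 time units;
  0.2 left the CEN almost silent.
* **Basal STEN drive.** `u_b = 0.2` sets spontaneous wave nucleation at
  a few percent field coverage in episodic bursts; it also guarantees
  firing when the cytoskeletal loops are silenced (the latrunculin-like
  preset), since the resting feedback balance subtracts about 0.06 from
  the effective amplitude.
* **Feedback gains.** `p1=1, p2=0.08` (fast local), `p3=0.05, p4=0.008`
  (slow global); the steady-state gain ratio
  $(p_4/p_3)/(p_2/p_1)$ is exactly 2, so *sustained* CEN activation
  ends up suppressing the STEN while *transient* activation boosts it.
  The small absolute magnitude matters: larger local gains make every
  CEN spark ignite the STEN and the field flashes synchronously instead
  of waving.
* **Global inhibitor.** `d_wc = Inf` marks $W_C$ as spatially uniform;
  the integrator then advances a single scalar driven by the spatial
  mean of $F_C$, which implements "sufficiently large diffusion"
  exactly, keeps its spatial variation identically zero, and leaves the
  explicit stability bound untouched.  A finite `d_wc` is also
  supported and then uses the ordinary stencil.

# Numerical scheme

Integration is explicit Euler--Maruyama: deterministic reaction plus
central-difference diffusion (3-point in 1D, 5-point in 2D; no-flux
boundaries mirror the edge value, periodic is optional), then per-site
Gaussian increments $\sigma_N\sqrt{dt}$ on $F_S$ and
$\sigma_c\sqrt{dt}$ on $F_C$.  Fields are floored at zero after each
step (they are concentrations).  The step obeys
$dt \le h^2/(4\max D)$ over the finite diffusion coefficients and
defaults to 0.4 times that bound.  Runs start from the deterministic
rest state with a 20-time-unit burn-in before measurements, which also
decorrelates the CEN's first firing cycle (without it the whole field
fires once in near-synchrony).  Every `FieldState` carries an RNG token,
so stepping equal states is bit-identical and a `(configuration, seed)`
pair reproduces a run exactly.

**Grid resolution.** 2D runs use unit spacing (the coarse 200 x 200 or
100 x 100 settings).  The 1D wave-theory experiments use a finer grid
(3,000 points at spacing 0.25): near the stopping level the front
narrows and slows, and on a unit-spacing lattice it would pin on the
grid before reaching the true stall point.  In the clamped-inhibitor
experiments the inhibitor never diffuses, so its (large) diffusion
coefficient is excluded from the step bound.

# Phase-plane wave theory

At clamped inhibition $r_0$ inside the bistable window the activator
rate has three roots $F_- < F_0 < F_+$.  The signed **net area**
$A(r_0) = \int_{F_-}^{F_+} f(F, r_0)\,dF$ (adaptive quadrature,
absolute tolerance $10^{-10}$) is the singular-limit proxy for front
speed: it is strictly decreasing in $r_0$, and its zero, found by
bisection to $10^{-9}$, is the stopping level `rStop()` at which the
two lobes balance and propagation stalls.  Only signs, zeros and
monotone order of this proxy are asserted -- the proportionality
constant to measured speed is not computed.

`speedThresholdScan()` measures speed directly: a deterministic 1D run
with the inhibitor clamped, a supra-threshold trigger at the left edge,
the front read off as the half-maximum crossing of the activator and
regressed on time over the middle 60% of the transit (robust to
start-up and stall transients).  The range is the distance from the
trigger to the last point whose peak activation reached 10% of the
global peak.  `simulatedStallLevel()` bisects the clamped level on the
sign of net front displacement; with `eps_s = 0.03` it lands within
about 1% of the bistable window of the analytic stopping level.

Stopping requires the inhibitor to out-disperse the activator.
`molecularDispersion()` uses the leading-order lifetime convention:
activator lifetime $1/a_{1}$, inhibitor lifetime $1/\epsilon$.
Configurations with deficient inhibitor dispersion propagate
indefinitely (the triggered pulse reaches the domain boundary).

# Perturbation presets

Acute recruitment and pharmacological perturbations are modelled as
scheduled linear parameter ramps over 10 time units
(`perturbationSchedule()`, `rampParameter()`).  The shipped preset
magnitudes are design choices, frozen so that each preset's directional
signature holds with margin:

| preset | ramp | signature |
|---|---|---|
| `inp54p` | `a3s` 4 → 5.6 | STEN threshold down; faster, longer-ranged, unbroken waves |
| `ras` | `a3s` 4 → 4.5 | the same direction, modest magnitude |
| `pkba` | `c1s` 5 → 7.5, `a3c` 4 → 6 | STEN threshold up + CEN threshold down; slower waves, more and smaller patches |
| `racgef1` | `a3c` → 8, `a1c` → 0.2, `c1c` → 1.5 | CEN jumps to a high stable state; global feedback first boosts, then durably suppresses STEN |
| `lata` | `sigma_c, s_c, p2, p4` → 0 | cytoskeleton silenced; only the basal drive `u_b` fires STEN |
| `fig3-wave-stopping` | none (`eps_s = 0.03`, `d_fs = 0.1`, `d_rs = 1`, noise off) | the deterministic 1D wave-theory configuration |

Speed and range comparisons between preset endpoints use triggered
deterministic runs (the per-wave measurement); patchiness and
suppression signatures use the full stochastic ramp runs with the
movie-level estimators.

# Level-set cell mechanics

The boundary is the zero level set of a signed distance field
(negative inside).  Stress on the boundary combines a protrusive term
linear in the local wave activity, surface tension against curvature,
and proportional volume control:
$\sigma_{tot} = g_p a - \gamma\kappa - g_V (A - A_0)/A_0$.  The
viscoelastic membrane/cortex pair

$$
\dot x_{mem} = -\tfrac{K}{D} x_{cor} + \left(\tfrac1D + \tfrac1B\right)\sigma_{tot},
\qquad
\dot x_{cor} = -\tfrac{K}{D} x_{cor} + \tfrac1D \sigma_{tot}
$$

is advanced with its closed-form constant-stress solution per step
(exact to machine precision at constant stress; the returned membrane
velocity is the step-averaged displacement rate), and at constant
stress the long-time membrane velocity is $\sigma/B$.  The level set is
advected with Godunov upwinding under a CFL bound
$\max|v|\,dt \le h/2$ and re-distanced every 10 steps by the
reinitialisation PDE with a subcell fix that pins interface cells to
their linear distance estimate -- without the fix, repeated
re-distancing alone drifts the enclosed area by more than 1% over a
thousand steps; with it the drift is below 1%.  The cortex displacement
is carried as a grid field sampled near the interface rather than on
explicit boundary nodes (it is a scalar along the normal; whether the
original formulation meant a vector field is unresolved, and the scalar
reading is adopted).

# Wave quantification

The estimators are applied identically to simulated readouts (the two
inhibitors, min--max scaled by fixed per-run constants recorded for
exact inversion) and to synthetic microscopy.

* **Peak distance**: both channels smoothed with a centred 19-pixel
  moving average (shrinking windows at the edges), argmax per channel
  (ties to the first index), signed by the propagation direction.  At
  coarse sampling the asymmetric two-peak band shifts under the fixed
  19-pixel window, so the line-scan fixture uses 0.1 um pixels --
  ordinary confocal sampling for this measurement -- where recovery is
  exact to the pixel.
* **Segmentation**: threshold at frame mean + 1 sd, drop objects under
  9 px, 8-connected labelling (4-connected labelling plus a union-find
  merge across diagonal contacts).
* **Front speed**: per boundary pixel of frame $n+1$, the distance
  transform of frame $n$'s edges gives the nearest-edge displacement;
  displacements outside [0.1, 5] length units are discarded as not
  being motion of the same front.  The acceptance band is stated in
  microns: the printed thresholds of the original protocol are treated
  as microns, the only physically plausible reading at cell scale, and
  are configurable.  Sub-pixel frame displacements quantise, so
  fixtures are generated at ~2 px/frame; movies whose front moves well
  under a pixel per frame are best analysed at a longer frame stride.
  The fraction of fastest pixels is the tail of kept displacements at
  least one video sd above the video mean.
* **Before/after reports** average 30 frames up to the event, skip 30,
  then average 30 more.
* **Puncta lifetimes**: objects of 4--100 px linked by nearest
  centroid within 2 px per frame; lifetime is
  `(last - first + 1) * frame_interval`.  Tracks touching the first or
  last frame are censored and dropped by default -- keeping them biases
  the mean low by more than the estimator's tolerance.

# The synthetic-data generator

`synthWaveMovie()` and friends emulate two-channel basal-surface wave
movies at a realistic scale: 0.5 um pixels, 3 s frames, waves at
0.3 um/s (~1.8 px/frame), a ~4 um diffuse one-peak signalling band, a
sharp two-peak cytoskeletal band (1.5 um peaks, 5 um apart, leading
peak brighter, an intermediate-intensity plateau strictly between the
peaks) with trailing puncta born as a spatio-temporal Poisson process
with exponential lifetimes (mean 10.8 s), additive Gaussian noise, and
machine-readable ground truth beside every pixel array.  Every
estimator has a closed-loop recovery test against that truth.

What the generator does **not** emulate: photon shot noise statistics
(optional), bleaching, cell-boundary occlusion, non-planar wave
geometry, or biological variability between waves.  Passing the
recovery suite therefore shows the estimators are correct on movies
whose structure matches their assumptions, not that they are robust to
every microscopy artefact.

# Problem sizes

The shipped test-suite and acceptance runs use: 3,000-point 1D grids at
spacing 0.25 for the stall-level comparison; 500--1,000-point grids for
the speed--threshold scans; 100 x 100 grids for the stochastic preset
runs (scaled down from the 200 x 200 production setting, which runs the
same code); 128 x 128 synthetic movies of 80--180 frames; and 96 x 96
level-set grids.  These sizes were chosen so the full suite exercises
every pathway at meaningful resolution while remaining quick to run on
one CPU.

# Known limitations

* The explicit scheme is first-order; near-threshold quantities (e.g.
  the simulated stall level) carry lattice and step bias at the
  percent level.
* The net-area speed proxy is exact only in the singular limit
  $\epsilon \to 0$; for `eps_s` well above 0.03 only the monotone
  ordering survives.
* The nearest-edge speed estimator aliases when distinct front edges
  approach within one frame displacement (e.g. the two sharp
  cytoskeletal bands); speed is therefore measured on the broad
  signalling band.
* Preset magnitudes are calibrated design choices, not fitted values;
  only directional claims are made for them.
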