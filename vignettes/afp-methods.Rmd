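---
title: "Methods: a virtual aerodynamic force platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual aerodynamic force platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afplatform)
```

## The measurement principle

An aerodynamic force platform is a rigid instrumented box enclosing the
object that generates a net fluid force $\mathbf{F}(t)$. Integrating the
momentum form of the Navier–Stokes equations over the box and applying the
no-slip/no-flow condition on the walls eliminates the unsteady and
convective bulk terms on the boundary, leaving

$$\mathbf{F}(t) \;=\; -\oint_S p\,\hat{\mathbf n}\,\mathrm dS
\;+\; \oint_S \bar{\tau}\cdot\hat{\mathbf n}\,\mathrm dS ,$$

with $\hat{\mathbf n}$ the outward normal. Load cells under the box read
this integral mechanically. Two dimensionless numbers certify the
idealization:

* the **compactness (AFP) number** $fL/c$ must be $\ll 1$ so pressure
  fluctuations reach the walls within a negligible fraction of a forcing
  period (`afp_number()`; the acoustic transit time itself is
  `acoustic_delay()` and satisfies $\mathrm{delay}\cdot f = fL/c$
  identically);
* the **Reynolds number** $UL/\nu$ must be $\gg 1$ so the viscous term of
  the wall integral is subordinate to pressure; the package bounds the
  shear a smooth uninstrumented panel would carry with the laminar
  flat-plate (Blasius) friction law $C_f = 1.328\,Re_L^{-1/2}$
  (`blasius_shear_force()`), which the test suite cross-checks against a
  shooting solution of the similarity equation
  $f''' + \tfrac12 f f'' = 0$.

The interior velocity field never has to be represented: it is eliminated
analytically on the control surface. That is the entire point of the
method, and it is why the package contains no general flow solver.

## Wall pressure of an interior point force

To verify that the wall integral really carries the whole force, the
package solves the incompressible pressure problem for a concentrated body
force. If the object generates $\mathbf F(t)$, the fluid receives the
reaction $-\mathbf F(t)\,\delta(\mathbf x - \mathbf x_0)$, and taking the
divergence of the momentum equation with $\nabla\cdot\mathbf u = 0$ gives

$$\nabla^2 p = \nabla\cdot\!\left(-\mathbf F\,\delta(\mathbf x-\mathbf x_0)\right),
\qquad \partial p/\partial n = 0 \text{ on the walls.}$$

Integrating the momentum equation over the box shows
$-\oint p\hat{\mathbf n}\,\mathrm dS = +\mathbf F$ exactly, for *any*
compactly supported interior source: the walls carry the full force. The
sign convention matters and is fixed throughout the package: `point_forcing`
holds the force the **object** generates, and `integrate_wall_force()`
returns exactly that vector.

`wall_pressure_point_force()` expands $p$ in the cosine eigenbasis of the
box (the Neumann eigenfunctions), with the source projected analytically
onto each mode. Numerical choices:

* **Regularized source.** A bare delta has a non-decaying cosine spectrum,
  so its pointwise series does not converge. The source is therefore
  mollified by an isotropic Gaussian of width `source_width` (default
  0.015 m — small against the 0.42–0.53 m box, large enough that 48 modes
  per axis resolve it spectrally). The momentum argument above is
  unaffected as long as the mollified source stays inside the box, so the
  recovered force is still exactly $\mathbf F$; physically a rotor or a
  flapping wing is not a point anyway. Randomized recovery tests sample
  source positions in the central 60 % of each dimension so the Gaussian
  tails stay interior.
* **Truncation.** Default 48 modes per axis; a convergence diagnostic (the
  share of modal amplitude in the outermost mode shell) is attached to the
  returned field, with a warning above 5 %. The test suite shows the force
  recovery error decreasing monotonically over 8, 16, 32, 48 modes and
  below $10^{-3}$ at the default.
* **Quadrature.** Composite Simpson on a 64-interval grid per wall
  direction, aligned with the cosine modes. On an aligned uniform grid the
  rule integrates every retained mode exactly, which is why a spatially
  uniform pressure integrates to the zero vector at machine precision
  (opposite walls cancel exactly).
* **Gauge.** The Neumann problem fixes $p$ only up to a constant. The
  constant mode is set to zero (zero volume mean); when the geometry has an
  aperture the constant is instead chosen so the mean pressure on the hole
  edge vanishes (hole open to atmosphere). On a closed surface a constant
  integrates to zero force, so the choice is cosmetic there; with a hole it
  affects only the component normal to the holed wall.
* **Independent oracle.** The test suite rebuilds the same field by the
  method of images — the reflection lattice of the regularized dipole, with
  moment components flipped once per reflection — and requires pointwise
  agreement below 1 % RMS on a wall grid for a near-wall source. The two
  constructions share no code.

**Apertures.** `integrate_wall_force()` assigns zero pressure to grid nodes
inside an aperture disc (that region is uninstrumented). Because the four
vertical walls have outward normals with zero vertical component, a hole of
*any* size in such a wall changes the recovered vertical force by exactly
nothing in this inviscid model — the tests verify bit-level insensitivity
for discs up to 22.3 % of the front wall. This is a statement about the
idealized model; on real hardware a hole also removes shear-carrying
surface.

## Compressibility: what "delay" means in a closed box

`compressible_delay_demo()` upgrades each cosine mode to a damped acoustic
oscillator $\ddot b + 2\zeta\omega_k\dot b + \omega_k^2 b =
\omega_k^2\,\alpha_k F(t)$ with $\omega_k = c\sqrt{\lambda_k}$, solved in
closed form from rest, and integrates the wall pressure into a force
history. Only the $(0,0,k_z)$ modes survive full-wall integration, so the
vertical force needs a single mode family.

Two delay measures are reported, because they answer different questions:

* the **steady-state cross-correlation delay** of the wall force against
  the applied sinusoid. For a rigid closed cavity driven far below its
  first acoustic resonance this is nearly zero: the cavity transfer
  function is real (standing waves), and only the modal damping
  ($\zeta_{\text{ac}} = 10^{-3}$ by default, enough to bound resonant
  transients that undamped modes would ring forever) contributes phase.
  The platform reads the interior force essentially instantaneously — the
  quantitative content of the compactness condition;
* the **onset arrival delay**: after the forcing switches on, the wall
  force stays zero until the wavefront arrives, and the demo measures the
  5 %-threshold crossing of the wall force relative to the same crossing of
  the applied force. This is the sound transit time from source to wall;
  expressed as a fraction of the forcing period it is of the order of the
  compactness number and grows monotonically with it across a log-spaced
  sweep (verified over $fL/c \in [10^{-3}, 10^{-1}]$).

A resonance flag is raised (not an error) when the forcing frequency lies
within 1 % of an acoustic mode.

## The instrument model

The platform structure is a sum of second-order resonators with unit total
DC gain (`modal_model`). Defaults follow the first-generation hardware: a
dominant 132 Hz vertical mode weakly coupled to a small 105 Hz mode,
realized as a 5 % participation; the reference beam is a single 138 Hz
mode. Damping ratios are not printed for the hardware; the default
$\zeta = 0.03$ is typical of stiff balsa sandwich structures and only
enters tests that compare against the same parameterized closed form.

Each resonator is discretized by the exact zero-order-hold state-space map
(matrix exponential), not a bilinear transform: at 1 ms sampling 132 Hz is
a sizeable fraction of Nyquist, and the ZOH map keeps the pole frequencies
and the DC gain exact, so ringdown zero crossings match the continuous
$e^{-\zeta\omega t}\sin(\omega_d t)$ solution and a static input is
reproduced exactly.

The load-cell stage models a statically determinate, equally preloaded
three-channel mount: the modal output plus preload is split equally across
channels, scaled by the raw sensor gain (the inverse of the linear
calibration coefficient, so that `apply_calibration()` — which multiplies
by the coefficient, once, with a state guard — restores unity end-to-end
gain), corrupted by seeded Gaussian noise (default RMS of one resolution
step, 2 mN), and mid-tread quantized. Raw channels therefore sit exactly on
the resolution lattice. Only the vertical axis is simulated; per-channel
imbalance and six-axis generalization are out of scope.

## Analysis pipeline choices

* **Filtering.** Fourth-order Butterworth low-pass, 30 Hz for the
  validation experiments and 60 Hz for flight (three times the 20 Hz
  wingbeat). Applied forward–backward by default: both signals of a
  validation pair receive identical zero-phase filtering, so the measured
  delay reflects the instrument, not the filter. The implementation
  demeans, pads with an odd reflection (about six cutoff periods) and
  restores the mean, so a constant passes exactly and start-up transients
  stay out of the data. A single-pass mode is retained for sensitivity
  checks.
* **Validation metrics.** Total impulse ratio (trapezoidal integrals),
  average force ratio (means), and delay from the cross-correlation peak
  with parabolic sub-sample interpolation, positive when the platform lags
  the reference. When the correlation peak is insignificant (below 0.2 of
  the zero-lag energy bound — e.g. two constant profiles whose fluctuation
  is independent sensor noise) the delay is reported as `NA` rather than a
  random lag.
* **Resonance identification.** Hann-windowed averaged periodogram
  (written in-package; no installed package exposes one) over the pop-test
  channel sum, peak within a search band, parabolic interpolation on log
  power. With 2048-sample segments at 1 kHz the resolution is about
  0.5 Hz.
* **Weight support.** Per-stroke duration-weighted means of $F/W$
  (trapezoid over each stroke window), wingbeats formed by pairing each
  downstroke with the following upstroke. The rule for a trailing unpaired
  stroke is not uniquely dictated by the stroke-direction convention at the
  end of a flight, so it is an explicit labelled option (`terminal =
  "alone"` reports it as an incomplete wingbeat, `"drop"` discards it)
  rather than a silent default. Take-off and landing bounds are inputs
  (from synchronized kinematics), never inferred from force.

## What the generators emulate — and what they do not

`gen_thrust_profile()` produces the validation inputs: constant,
semi-sinusoidal (a mean-offset sinusoid clipped at zero, since a rotor
cannot pull; at default amplitudes the clip never engages) and a smoothed
seeded random walk standing in for a hand-controlled profile. The preset of
84 modulation periods at 0.125–0.5 Hz mirrors the laboratory protocol; the
end-to-end drivers default to 6 periods and 10 replicates, a desk-scale
choice that leaves the closure statistics unchanged in expectation.

`gen_bird_flight()` produces a perch-to-perch flight of a 28 g,
20 Hz-wingbeat parrot-like bird: per wingbeat a half-sine downstroke hump
peaking at twice body weight and a near-zero upstroke plateau (5 % of body
weight by default), ±5 % seeded cycle-to-cycle amplitude jitter, optional
raised-cosine leg-push impulses at take-off and landing, eight wingbeats by
default (a 0.28 m hop lasts well under a second; the count is a documented
guess, configurable). A trapezoid hump is available behind a flag.

These waveforms are *stand-ins with the right gross structure* — correct
peak multiples, stroke timing, asymmetry and non-negativity — not
reproductions of any real bird's within-stroke force shape, which is why
parameter-recovery tests compare the pipeline output against the
generator's own ground truth passed through the same filter, and why
in-vivo wingbeat-average values are never used as targets. Passing tests
therefore demonstrate that the *measurement chain* is faithful, not that
the synthetic bird is.

The simulated validation closes at impulse and force ratios of
$1.000 \pm 0.005$; it does **not** reproduce the percent-level high bias a
real platform shows against a real reference beam, because that bias stems
from uninstrumented shear on physical panels, which the ideal simulation
deliberately omits (the Blasius bound quantifies its magnitude instead).

## Fluid constants

`fluid_properties()` defaults to $\rho = 1.204$ kg m$^{-3}$,
$\nu = 1.48\times10^{-5}$ m$^2$ s$^{-1}$, $c = 340$ m s$^{-1}$. The quoted
enclosure-height Reynolds number of the working conditions
($\approx 2.7\times10^4$ at $U = 0.95$ m s$^{-1}$, $L = 0.42$ m) is
consistent with this standard-air viscosity rather than the 25 °C value
($1.56\times10^{-5}$); both are available — `standard_air(25)` interpolates
tabulated properties — and the Blasius bound uses 25 °C air, matching the
hotwire measurement conditions it represents. The Blasius reference length
defaults to the 0.420 m panel dimension along the flow; the orientation is
configurable since it is not dictated by the geometry.

## Problem sizes

The shipped tests and the acceptance script run the spectral solver at 48
modes per axis on 64-interval wall grids (about 0.1 s per solve), the image
oracle at 5 reflection shells on a 33×33 wall grid, the validation closure
at 4 profiles × 10 replicates × 6 modulation periods sampled at 1 kHz, and
flights of 8 wingbeats at 5 kHz ground truth. These sizes were chosen so
the whole suite completes in well under a minute while every tolerance in
it is met with an order of magnitude to spare; all of them are arguments,
not constants.

## Known limitations

* Inviscid, incompressible interior idealization: no boundary layers on
  the walls, no wake or rotor-jet structure, no turbulence. Shear enters
  only as the scalar Blasius bound.
* The compressible demonstration is one-dimensional in effect (vertical
  modes) and uses light modal damping as a numerical device, not a model
  of room acoustics.
* Only vertical force is simulated and analyzed; moments and horizontal
  components are out of scope.
* Stroke segmentation is an input; no kinematic or force-based stroke
  detection is attempted.
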