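---
title: "Simulating a wrist-worn coincidence detector for blood time-activity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a wrist-worn coincidence detector for blood time-activity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(wristpet)
```

## The problem

Quantitative PET kinetic modelling needs the arterial input function — the
radiotracer concentration in arterial blood over time.  The gold standard,
continuous arterial sampling through a radial-artery cannula, is invasive
and costly; image-derived input functions need large vessels in the field
of view and heavy partial-volume processing.  A small ring of scintillator
blocks worn at the wrist could instead count annihilation photons from the
radial and ulnar arteries directly.  `wristpet` implements a desk-scale
simulation pipeline for asking whether such a device sees enough signal:
dynamic tracer kinetics in a forearm phantom, simplified 511-keV photon
transport, a digitizer and coincidence sorter, and count-rate analysis
across detector configurations.

The package deliberately stays far below a general-purpose Monte Carlo
code.  The quantities of interest here — singles fractions across blocks,
trues ratios between source positions, gains between ring counts — are
driven by solid angles and bulk attenuation, which a simplified transport
reproduces.  Absolute count rates depend on digitizer constants that a
full simulation toolkit buries in its defaults, and are only meaningful
here as orders of magnitude.

## The blood curve model

All source activity derives from a piecewise linear-exponential model of
the blood time-activity curve (BTAC):

$$
C(t) = \begin{cases}
0 & t \le t_0 \\
a\,t + b & t_0 < t < t_1 \\
c_1 e^{d_1 t} + c_2 e^{d_2 t} & t \ge t_1
\end{cases}
$$

The package ships fitted parameter sets for arterial and venous whole-blood
curves of two tracers, O-15 labelled water (1000 MBq nominal injection)
and F-18 fallypride (250 MBq), stored verbatim as published.  Two
conventions deserve attention:

* **Sign of the exponents.**  The rate constants $d_1, d_2$ are tabulated
  as negative numbers while the model is sometimes written with
  $e^{-d t}$.  Taken literally together these would make the tail grow
  without bound, so the package evaluates the tail as
  $c_1 e^{d_1 t} + c_2 e^{d_2 t}$ with the negative values used as-is,
  which yields the physically sensible decaying tail.
* **Breakpoints.**  $t_0$ and $t_1$ are not part of the published
  parameter sets.  `solve_breakpoints()` derives them as the clamped zero
  crossing of the ramp, $t_0 = \max(0, -b/a)$, and the first ramp/tail
  intersection (bracketing scan plus bisection to $10^{-9}$ relative
  tolerance).  This is the only choice that makes the curve continuous and
  single-peaked, and continuity at $t_1$ then holds by construction —
  also inside `fit_aif()`, which re-solves the breakpoints at every
  optimiser step.

Concentration units are not stated with the published fits; the package
adopts kBq/ml, consistent with the expectation of sub-500-kBq/ml
concentrations at the wrist, and exposes the unit tag on every curve
object.  Half-lives (O-15: 122.24 s, F-18: 6586.2 s) are standard nuclear
data.  Note two quirks that are shipped faithfully rather than corrected:
the 15O arterial intercept $b > 0$ puts a step at $t = 0$, and both venous
fits have ramp zero-crossings near 171 s, so venous activity is exactly
zero before then (plus the 5 s venous return delay).

```{r aif}
tr <- tracer("O15-water")
autoplot(aif_curve(tr$arterial, step = 0.5, horizon = 250)) +
  ggplot2::ggtitle("15O-water arterial input function")
```

`fit_aif()` refits the model to sampled curves.  The parameters span ten
orders of magnitude and a misplaced ramp onset creates a local minimum in
which the curve collapses to zero, so the fitter first pins the ramp by
linear regression on the rising limb and the fast tail by log-linear
regression, then runs Levenberg-Marquardt in two stages (dominant
parameters first, then all six) with each parameter scaled by its current
magnitude.  At 1% multiplicative noise the ramp and fast-tail parameters
are recovered to within a few percent; the small slow component
($c_2 \approx 2$ against peaks of $10^3$–$10^5$) is not identifiable under
noise and is reported as fitted.

## Phantom and flow

The forearm is a 20-cm-long, 8-cm-diameter water cylinder containing two
2.5-cm bone cylinders, two 2.5-mm arteries and two 1.5-mm veins, all
z-aligned.  The transaxial vessel and bone coordinates are published only
as a schematic; the defaults place the bone centres at $(\pm 1.8, +0.5)$
cm — reading the stated 1.1 cm bone separation as the surface-to-surface
gap — and the vessels on the volar aspect at $y = -2.5$ cm.  All
coordinates, radii and attenuation coefficients are configurable.  The
511-keV attenuation coefficients (water 0.0958/cm, cortical bone
0.178/cm, blood 0.101/cm) are standard narrow-beam values, adopted
because the source material does not state them.

Blood moves as 1-D plug flow.  Arteries flow in $+Z$; for the closed-ring
baseline they carry a uniform 15 cm/s flow, and for the half-ring studies
a pulsatile profile.  The published studies reference a measured
radial-artery velocity profile that is not reproduced in print, so the
package uses a parametric single-beat stand-in
$v(\varphi) = v_{dia} + (v_{sys}-v_{dia})\max(0, \sin(\pi\varphi/w))^2$
with defaults $v_{sys} = 40$ cm/s, $v_{dia} = 5$ cm/s, systolic width
$w = 0.35$ and a 1 s period (60 bpm).  Veins return at a uniform 5 cm/s
with the venous curve delayed 5 s.  Advection is Lagrangian: the
concentration at distance $x$ from the inlet is the inlet curve at the
retarded time $\tau$ with
$\int_\tau^t v = x$, found by monotone bisection; there is no axial
dispersion inside the phantom — the dispersion of the venous return is
carried entirely by the separate venous parameter set, as in the source
study design.  `activity_timeline()` discretises each vessel into 0.5-cm
segments and 0.1-s bins (a convergence test shows the peak total activity
changes by under 0.5% on halving the segment length).

## Photon transport and detection

Each decay emits two back-to-back 511-keV photons (uniform orientation;
positron range and acollinearity are neglected — sub-millimetre effects
irrelevant at count-rate level).  Transport through the phantom uses the
exact piecewise optical depth along the ray (all volumes are z-aligned
cylinders, so chords have closed forms).  The free path is sampled from
the exponential law; an interaction is Compton with probability 0.99
(photoelectric absorption otherwise), the scattering angle is drawn from
the Klein-Nishina distribution at the current energy by rejection, and
the energy updates with the Compton formula.  At most one scatter is
followed — a second interaction absorbs the photon.  For an 8-cm phantom
viewed by a half-ring this single-scatter approximation loses only a
small multiple-scatter correction while keeping transport O(1) per
photon.  The energy dependence of the attenuation coefficients between
511 and ~170 keV is also neglected.

Detectors are monolithic 2.45 x 3.0 x 2.0 cm$^3$ blocks.  The closed ring
(`build_wristpet1()`) has 14 blocks; the open design
(`build_wristpet2()`) keeps the eight volar blocks and stacks 1-4 axial
rings at 3-cm pitch.  The inner ring diameter is not published beyond the
requirement of fitting a human wrist; the default is 11 cm, the smallest
round figure accommodating 14 blocks of 2.45 cm width.  Block indexing increases
clockwise with block 1 spanning the top of the ring: this puts the
retained arc 4-11 symmetric about $-Y$, including the two
horizontal-equator blocks.  (The alternative reading — block 1 *centred*
on $+Y$ — cannot give a symmetric eight-block volar arc; the symmetric
convention matches the open-ring schematic.)

A photon is tested only against the first block it intersects, with
interaction probability $1 - e^{-\ell/\lambda}$ for chord $\ell$ and the
crystal's 511-keV attenuation length $\lambda$.  Any interaction deposits
the full incident energy: there is no partial-deposit spectrum, so
scatter rejection is carried by phantom-scattered photons arriving with
reduced energy.  Energies are blurred with a Gaussian whose FWHM scales
as $R \cdot 511\,\mathrm{keV}\cdot\sqrt{511/E}$ (resolution $R$ quoted at
511 keV), then gated by a 350-650 keV window (closed at both ends) — the
digitizer defaults referenced by the source study are unpublished, so
these GATE-like defaults are adopted and configurable.  Timestamps are
decay times plus 1 ns Gaussian jitter (time of flight neglected); the
jitter keeps the coincidence window meaningfully exercised.  Each block
has non-paralyzable deadtime, defaulting to three crystal decay times —
a choice that ties the unpublished deadtime constant to tabulated crystal
physics while remaining overridable.

The coincidence sorter opens a window at the earliest unconsumed single
and collects everything within the crystal-specific coincidence window;
pairs on distinct blocks are kept, and multiples are kept only if *all*
pairs are good ("keep if all are good"), otherwise discarded.
Coincidences classify as true (same decay, neither photon scattered),
scattered (same decay, any scatter) or random (different decays), and
`necr()` computes $T^2/(T+S+kR)$ with $k = 1$.

## Experiments and problem sizes

The four experiment drivers reproduce the study designs end to end from a
config and a seed: `run_crystal_comparison()` (five scintillators, shared
source realisation, per-material digitizer physics),
`run_necr_experiment()` (decaying 14 MBq F-18 point source — 1 mm$^3$,
modelled as an equal-volume cylinder — at $Y = -1/-2/-3$ cm in the
water-only phantom), `run_btac_experiment()` (arterial-only, venous-only
and combined runs) and `run_ring_scaling()` (1-4 axial rings, cross-ring
coincidences allowed, gains against the single-ring reference).

Every run is desk-scale.  BTAC sources are scaled by a history factor
(1/100 for the volar-fraction scenario; 1/500 for the four-ring and
five-crystal sweeps so a full sweep stays at a few million decays; 1/20
for the low-activity 18F runs) and simulated over 60-300 s horizons;
these sizes give
roughly $10^5$-$10^6$ singles per run, enough that the fractional
quantities of interest carry percent-level counting error.  The
decaying-source experiment instead keeps the *full* instantaneous
activity and shortens each acquisition window (12 windows whose start
times are evenly spaced over five half-lives, so window activities are
log-spaced; about $6\times10^4$ expected decays per window): randoms
scale with the square of the true rate and deadtime with the true
per-block rate, so those effects are only faithful at the real activity.
The NECR peak is located by quadratic interpolation through the three
samples around the maximum (on log activity), falling back to the edge
sample when the maximum is not interior — the source study does not state
its peak-finding method.

Ratios between matched runs (trues ratios across positions, ring-count
gains) are scale-invariant, which is what makes the desk-scale faithful
for the headline comparisons; absolute sensitivities in cps/kBq are
reported as computed at the simplified physics and are expected to sit
above measured-system values because every crystal interaction counts as
a detection.

## What the generator does and does not emulate

The kinetics and flow modules *are* the study's synthetic-data generator:
they stand in for an automated blood-sampling measurement, so "truth" is
available exactly and recovery can be tested.  They emulate bolus
arrival, dispersion and delay of the venous return, pulsatility, and
nuclide decay.  They do not emulate intra-subject curve variability,
metabolites, plasma-to-whole-blood ratios, dispersion inside the phantom
vessels, superficial veins, or patient-specific vessel geometry.  Passing
tests therefore demonstrate the *detector physics and counting chain*
under clean, known inputs — not robustness to physiological variability.

## Numerical choices and degenerate inputs

* Breakpoint solving: 4096-point bracketing scan then `uniroot` at 1e-9
  relative tolerance; a tail that never meets the ramp raises a
  no-intersection error (600 s default horizon).
* Advection: retarded times by 64-step bisection (sub-nm displacement
  tolerance); quadrature of tabulated waveforms is trapezoidal on 512
  points per beat.
* Transport: optical-depth inversion by 48-step vectorised bisection on
  the piecewise-linear depth function.
* Klein-Nishina sampling: rejection against a uniform envelope of 2
  (exact; acceptance ~0.5 at 511 keV).
* Deadtime and the sorter are sequential by definition and implemented as
  explicit per-block / per-window passes; `tau = 0` is the identity, and
  a simultaneous event at an accepted timestamp is not blocked (the dead
  interval is open at its left end).
* Degenerate inputs error early: zero direction vectors, negative times
  or pathlengths, constant samples in `fit_aif()`, unsorted event times,
  overlapping or out-of-body phantom volumes.

All stochastic entry points take a seed; a fixed config and seed
reproduce event lists bit for bit, and chunked processing (about
$2\times10^5$ decays per chunk) bounds memory without changing results.

## Known limitations

* Singles-rate *gains* from added axial rings are bounded near the axial
  coverage ratio in this model, because singles scale with the detector
  solid angle integrated along the vessel; the published gains are
  superlinear in ring count, which a solid-angle-plus-attenuation model
  cannot produce.  Coincidence gains, which grow with the square of the
  axial acceptance and with cross-ring combinations, are reproduced.
* Crystal efficiency differences reduce to attenuation length, energy
  resolution, coincidence window and deadtime.  Materials that differ in
  those tables differ here; effects that would equalise them (light
  yield, photofraction, crystal-level scatter) are out of scope.
* The volar singles fraction is sensitive to the unpublished vessel
  depth; with the default $y = -2.5$ cm placement the simplified chain
  concentrates a few percentage points more of the singles on the volar
  arc than the published 70-75% band.
* No image formation, no depth of interaction, no inter-crystal scatter,
  no pile-up beyond non-paralyzable deadtime.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes the three headline quantities (volar
singles fraction, trues ratio between source depths, 4-ring coincidence
gain) from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
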