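---
title: "Methods: synthetic aortic haemodynamics and the shear stress ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic aortic haemodynamics and the shear stress ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortassr)
```

## What this package models

Ascending-aorta aneurysms — particularly in connective-tissue disease such
as Marfan syndrome — are conventionally monitored by maximum diameter, a
criterion known to miss a large fraction of dissections. Haemodynamic
markers extracted from time-resolved velocity fields offer a complementary
view: an eccentric, angled systolic jet and a strong helical secondary flow
leave a signature in the *wall shear stress* (WSS), and the dimensionless
**shear stress ratio**

$$\mathrm{SSR} = \frac{|\mathrm{WSS}_{circ}|}{|\mathrm{WSS}_{ax}|}$$

— circumferential over axial wall shear — quantifies how much the near-wall
flow rotates in plane relative to how much it progresses down the vessel,
while cancelling the strong dependence of axial WSS on lumen diameter.

Producing such markers from subject-specific simulations requires two
calibration loops: wall stiffness must reproduce the measured **pulse wave
velocity** (PWV) through the Moens–Korteweg relation

$$\mathrm{PWV}^2 = \frac{E\,h}{2\rho\,r},$$

and the outlet boundary (a two-element Windkessel,
$Q = P/R + C\,\mathrm{d}P/\mathrm{d}t$) must reproduce the measured
descending/ascending flow split. This package implements the full chain at
desk scale: parametric vessel geometry, an analytic pulsatile velocity-field
generator with an MRI-like degradation model, a 1D elastic-tube pulse-wave
surrogate, both calibration loops, the marker extractors, and the
regional/cohort statistics — every piece with closed-form or enumerated
oracles so the whole pipeline is testable without any clinical data.

A full 3D fluid–structure-interaction solver is deliberately out of scope;
the 1D surrogate exists to exercise the calibration logic with the same
interfaces and stopping rules at a computational cost of seconds.

## The 1D pulse-wave surrogate

The tube solver advances the standard area–flow system

$$\partial_t A + \partial_x Q = -g(x)\,p, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -\,8\pi\nu\,\frac{Q}{A},$$

with a two-step Lax–Wendroff scheme on a uniform grid (200 nodes by
default). The elastic tube law is
$p(A) = \beta/A_0\,(\sqrt{A} - \sqrt{A_0})$ with
$\beta = \sqrt{\pi}\,E\,h$, chosen so that its linearized wave speed is
**exactly** $c_0 = \sqrt{E h / (2\rho r)}$ — the calibration loop must be
consistent with the Moens–Korteweg relation at its fixed point, so the
$(1-\nu^2)$ thick-wall factor is intentionally omitted and the Poisson
ratio (0.45) and wall density (1100 kg m⁻³) are carried as metadata only.
The density in the relation is the fluid density (1050 kg m⁻³), blood
being treated as an incompressible Newtonian fluid with
$\mu = 0.035$ kg m⁻¹ s⁻¹ throughout.

The inlet imposes the prescribed flow waveform through the backward
characteristic; the outlet couples into the Windkessel through the forward
characteristic with an implicit-Euler pressure update. A distributed
pressure-driven sink ($-g(x)p$, configurable position and total
conductance) stands in for the supra-aortic branches, so the
descending/ascending flow split can be exercised without branch geometry.

**Wall viscoelasticity.** A purely elastic tube truncated by a lumped
outlet, driven by a prescribed-flow inlet, is a nearly undamped resonator:
its $2L/c$ cavity modes ring through diastole. Real aortic walls are
viscoelastic, so the solver includes a Voigt-type term (wall viscosity
$\varphi$, default 500 Pa·s, momentum diffusion solved implicitly and
unconditionally stably). It damps the ringing without measurably changing
the transit speed; `wall_viscosity = 0` recovers the elastic tube. The
default sits at the lower end of reported aortic wall-viscosity scales and
was fixed once for numerical robustness across the full stiffness range —
it is not a fitting knob.

## Measuring the pulse wave velocity

The clinical definition divides the distance between two planes by the
travel time of the systolic wave between them, and `measure_pwv()`
implements the two waveform-timing conventions: systolic **peaks** with
parabolic sub-sample refinement (25 ms frames are too coarse for a raw
argmax), and the systolic **foot** by the intersecting-tangent
construction.

On the surrogate, however, waveform timing at periodic steady state is
fundamentally ill-posed: the tube is electrically *short* (the pulse
wavelength, $c \times T \gtrsim 6$ m, is twenty times the tube length), so
all broad waveform features are shaped by the boundary dynamics rather
than by transit. Empirically, the terminal flow peak moves *earlier* than
the inlet peak (the Windkessel's $C\,\mathrm{d}P/\mathrm{d}t$ term peaks
on the pressure upstroke), and foot timing inflates by the same mechanism.
In the 3D setting this is mitigated by distributed branch outflows and
damping; in a single 1D tube it is not.

The calibration loop therefore uses a strictly causal instrument,
`pwv_from_arrival()`: each simulation starts from the diastolic operating
state (steady base flow, charged Windkessel), so during the first cycle the
systolic wavefront sweeps the tube exactly once before any reflection
exists. The time at which flow first rises 1% of the systolic range above
base is recorded at every grid node, and the wave speed is the inverse
slope of arrival time against distance, fitted over the proximal half of
the tube (distal crossings are advanced by the wavefront's own outlet
reflection, which reaches a station at distance $x$ a time $2(L-x)/c$
behind the front). This lands within ~6% of $c_0$ across the entire
6.2–20.7 m s⁻¹ clinical range and is monotone in $E$, which is what the
loop needs.

## The two calibration loops

**Stiffness.** $E_0$ comes from the Moens–Korteweg formula applied to the
target PWV; each iteration simulates, measures the transit PWV, and stops
when the relative error is within ±5%. The update is multiplicative,
$E_{i+1} = E_i\,(\mathrm{PWV}_{target}/\mathrm{PWV}_i)^2$: because
$\mathrm{PWV} \propto \sqrt{E}$ to good accuracy, the log-domain iteration
contracts almost immediately, and the loop converges in one or two
iterations over the whole clinical range (the ≤3-iteration behaviour of
the original procedure). Re-applying the Moens–Korteweg formula to the
*measured* PWV — a literal reading of the published iteration — is a fixed
point of the formula itself rather than of the matching problem; it is
retained behind `update = "printed"`. If the sign of the error oscillates
without shrinking, the log-E step is damped by 0.7 (a robustness guard
that the default configuration never triggers).

**Flow split.** The published procedure tuned $R$ and $C$ by hand until
the simulated descending/ascending flow ratio was within ±5% of the
measured one. Here `calibrate_windkessel()` automates this with secant
iteration on $\log R$; the achieved ratio is monotone decreasing in $R$
(raising outlet resistance diverts flow through the branch sink), so the
secant converges in a handful of evaluations. A flow ratio cannot identify
$R$ and $C$ jointly; the compliance is closed by fixing the time constant
$RC$ to one third of the cycle, a typical arterial value. Cycle-mean flows
define the ratio.

## The synthetic data world

The generator produces analytic velocity fields whose markers are known in
closed form, which is what makes every extractor testable.

* **Axial jet**: a parabolic profile of effective radius
  $R_{jet} = R - d$, recentred a distance $d$ (the *jet offset*) from the
  centerline and tilted by the *jet angle*; the profile is flow-normalized
  so the plane integral equals the prescribed waveform exactly. With
  `womersley_harmonics > 0` the steady profile is replaced by the
  flow-normalized Womersley solution per harmonic (validated against an
  independent finite-difference solution of the radial boundary-value
  problem).
* **Waveform**: squared-sine ejection over a systolic fraction (default
  0.35 of a 1000 ms cycle) on a diastolic base flow; mean flow 83 mL s⁻¹
  (≈5 L min⁻¹ cardiac output) and peak/mean ratio 4 by default.
* **Secondary flow**: an azimuthal swirl about the jet core,
  $u_\theta = k\,\rho\,(R_{jet} - \rho)$ (SI units, $k$ in s⁻¹ m⁻¹). This
  profile vanishes at the wall (no slip) and at the core, exerts a
  circumferential wall shear of exactly $\mu k R$ on a centred jet, and
  keeps the speed maximum at the jet core provided
  $k < 2\sqrt{2}\,Q_{peak}/(\pi R_{jet}^4)$ — the condition under which
  the generator's ground truth (offset, angle, peak velocity) remains
  exact. A quadratic swirl that does *not* vanish at the wall would break
  the no-slip assumption every image-based WSS estimator rests on, which
  is why this form was chosen.
* **MRI degradation**: box averaging to 2.5 mm voxels and 25 ms frames
  (the 400 mm field of view maps to the 160³ acquisition matrix), plus
  Gaussian velocity noise with the standard phase-contrast propagation
  $\sigma = \mathrm{venc}\sqrt{2}/(\pi\,\mathrm{SNR})$ per component
  (venc 200 cm s⁻¹, SNR 20 by default) and optional phase wrapping.
* **Cohorts**: three groups (controls, stable and dilating aneurysms)
  with per-group lumen radii following the published diameters
  (≈12.75 / 14 / 18.4 mm), target PWVs drawn within the published
  per-group ranges inside 6.2–20.7 m s⁻¹, wall thickness $r/10$
  (consistent with the published PWV–stiffness pairs), and increasingly
  eccentric, angled and helical flow. The helical strength multipliers
  (1×, 2×, 6× of 800 s⁻¹ m⁻¹) are package configuration chosen to
  reproduce the *qualitative* group ordering of the distal-ascending SSR
  distribution; they are not published effect sizes, and a green
  separation test establishes only that the pipeline can recover an
  encoded group effect, not that real cohorts separate.

What the generator does **not** emulate: k-space artefacts, eddy-current
phase offsets, breathing/gating artefacts, branch flow, turbulence, or any
fluid-dynamic feedback between the swirl and the jet (the fields are
kinematic constructions, not Navier–Stokes solutions).

## Wall shear stress estimation

At every surface vertex the wall-tangential velocity is sampled along the
inward normal at depths $\delta, 2\delta, 3\delta$ (default
$\delta$ = one voxel) and the wall gradient is estimated by least squares
anchored at zero wall velocity (no slip). The default fit includes a
quadratic depth term and reports the linear coefficient: the plain
anchored straight-line slope carries a first-order bias of about
$2.6\,\delta/R$ on curved profiles (8% at $\delta = 0.8$ mm in a 12.5 mm
vessel), whereas the anchored quadratic is exact for parabolic near-wall
profiles — both the Poiseuille jet and the swirl law — and passes the 5%
closed-form checks at realistic depths. `fit = "linear"` is retained for
comparison. The WSS vector $\mu\,\partial v_t/\partial n$ is projected
onto the axial direction (centerline tangent projected into the local
tangent plane, positive downstream) and the circumferential direction
(normal × axial).

SSR uses component magnitudes with a floored denominator:
$|\mathrm{WSS}_{ax}|$ below $10^{-3}$ Pa (flow-reversal instants,
stagnation) flags the vertex, and flagged or invalid vertices are excluded
from every regional statistic. SSR is exactly invariant under uniform
velocity scaling and under reversal of the axial sign convention; a signed
variant is available.

## Regional and cohort statistics

Quadrant labels divide each circumference into four 90° sectors about a
user-supplied anterior axis projected into the section plane (the
patient-axes convention of the imaging world is not available to a
synthetic tube, so the reference direction is explicit configuration);
both the anterior/left/posterior/right and the
anterior/interior/posterior/exterior label sets are supported, and the
mapping between them is a labelling choice, not an anatomical claim. The
ascending segment is additionally split at the arithmetic midpoint of its
arc-length range into proximal and distal halves; the distal half is the
default region for the cumulative-frequency analysis, summarized by the
90th percentile (closest-ranks linear interpolation).

Group comparison follows the published recipe: Kruskal–Wallis (tie
corrected) with either the chi-square approximation or an exact
permutation p-value — for tie-free data the exact null distribution
depends only on the group sizes, so the 34,650 assignments of a 4+4+4
cohort are enumerated once and cached. Scheffé post hoc contrasts are run
on the original measured values, as published; pairing a rank-based
omnibus test with a variance-based post hoc is unusual, so Dunn's
rank-based test is provided as an alternative. Group tables report
mean ± s.e.m.

## Numerical choices and degenerate inputs

* Calibration stopping rules: ±5% on both loops (the published values);
  iteration caps 20 (stiffness) and 30 (flow split).
* Windkessel ODE: RK4 at 2000 steps/cycle, cycles repeated until the
  relative L2 cycle change is below 0.1%.
* 1D solver: CFL number 0.8 against $c_0$ plus a generous convective
  margin; an explicit user time step that violates the CFL bound is
  rejected with the required step named; non-finite states abort with a
  diagnostic. Periodicity is declared below 0.5% relative L2 cycle change
  and one further cycle is recorded.
* Peak timing: parabolic refinement around the discrete maximum; flat
  waveforms are flagged, not silently timed. Degenerate wave timing
  (non-positive delay) is an error, not a wrapped pseudo-velocity.
* Rotation-minimizing frames (double reflection) rather than Frenet
  frames: quadrant axes must not flip on straight sections. Tube
  construction rejects non-monotone centerlines and radii exceeding the
  local radius of curvature.
* Jet offsets must stay inside the lumen ($d < R$); points outside the
  lumen return zero velocity by contract.

## Known limitations

The surrogate is a single uniform tube: no taper, no branches, no 3D
secondary-flow physics, and its absolute SSR values are estimator- and
resolution-dependent (as they are for any image-based WSS estimate, which
is why cohort comparisons are made within a fixed pipeline). The
cold-start arrival PWV is the transit speed at the diastolic operating
point, slightly above $c_0$; the calibration absorbs this bias by
construction. Cohort effect sizes are stated configuration, and the
statistical suite demonstrates calibration of the tests themselves (size
of the exact Kruskal–Wallis under the null), not clinical discrimination.
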