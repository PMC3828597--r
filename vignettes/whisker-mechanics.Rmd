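---
title: "Quasi-static mechanics of tapered whiskers contacting a pole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-static mechanics of tapered whiskers contacting a pole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrissa)
```

## The model

Rodent facial whiskers are thin elastic beams, very close to linearly
tapered truncated cones, with an intrinsic curvature well described by a
parabola. When a whisker is rotated against an object it deflects, slides
along the object, and eventually detaches. This package computes those
interactions in a plane, in the quasi-static regime: at every instant the
whisker shape is the static equilibrium for the instantaneous boundary
conditions. The regime is appropriate for slow drives (fractions of a Hz
against a pole) and breaks down during the few milliseconds of fast motion
that follow a slip, which are outside the model's scope.

The whisker is a truncated cone of length $L_w$ with base radius
$r_\mathrm{base}$ and tip radius $r_\mathrm{tip}$, virtually extended to a
full cone of length $L = L_w\, r_\mathrm{base}/(r_\mathrm{base} -
r_\mathrm{tip})$, so the radius at arclength $s$ is $r_w(s) = (L - s)\,
r_\mathrm{base}/L$ and the area moment of inertia is $I(s) = \pi
r_w(s)^4/4$. For typical mouse whisker dimensions the bending stiffness
$E\,I(s)$ falls by five orders of magnitude from base to tip; this
gradient is the subject of the whole analysis, since a hypothetical
cylindrical whisker ($r_w$ constant) behaves qualitatively differently.
The undeflected shape is the parabola $y = A\,(x - x_v)^2$ in
whisker-local coordinates, traversed by arclength from the base.

The contacted object is a cylindrical pole of radius $r_\mathrm{pole}$
perpendicular to the plane, i.e. a circle. Contact is point-like and
frictionless: the pole exerts a force of magnitude $F$ on the whisker,
normal to the whisker at the contact point $(x_\mathrm{obj},
y_\mathrm{obj})$, which lies on the circle at the position parameterised
by the contact angle $\theta_\mathrm{obj}$. The static Euler–Bernoulli
equation with intrinsic curvature $\kappa_i(s)$,
$$\frac{d\theta}{ds} = \kappa_i(s) + \frac{M_z(s)}{E\,I(s)},\qquad
\frac{dx}{ds} = \cos\theta,\qquad \frac{dy}{ds} = \sin\theta,$$
with $M_z$ the out-of-plane bending moment of the contact force about the
point $(x(s), y(s))$, is rescaled by $\sigma = s/s_\mathrm{obj}$ onto the
fixed interval $[0, 1]$, where $s_\mathrm{obj}$ is the (unknown)
arclength from base to contact. The three unknown constants $F$,
$\theta_\mathrm{obj}$ and $s_\mathrm{obj}$ are appended to the state with
zero derivatives, giving a six-equation boundary-value problem: base
position and angle prescribed at $\sigma = 0$; position on the pole
circle and tangency ($\theta(1) = \theta_\mathrm{obj}$) at $\sigma = 1$.

## Numerical treatment

The boundary-value problem is solved by iterative shooting. The system is
integrated from $\sigma = 0$ to $1$ with an adaptive Runge–Kutta scheme
(`deSolve`, right-hand side compiled in C; relative tolerance $10^{-9}$,
absolute $10^{-12}$) and the three boundary mismatches at $\sigma = 1$
(positions scaled by $L_w$, angle in radians) are driven below
`shoot_tol` ($10^{-9}$) by a damped Newton iteration with a
finite-difference Jacobian. The Jacobian is recycled between nearby solves
(chord iterations) and rebuilt when the contraction degrades, which
removes most of the integrations during continuation. The Newton unknowns
are nondimensionalised: forces by $E I(0)/L_w^2$, arclengths by $L_w$.

Two parameterisations of the same problem are used:

* **fixed pose** — base angle $\theta_0$ prescribed, unknowns $(F,
  \theta_\mathrm{obj}, s_\mathrm{obj})$. This is the physical question
  ("the base is here; what is the shape?") and generically has two
  solutions, one stable and one unstable.
* **fixed contact angle** — $\theta_\mathrm{obj}$ prescribed, unknowns
  $(F, s_\mathrm{obj}, \theta_0)$. Along a solution branch
  $\theta_\mathrm{obj}$ varies monotonically while the push angle folds
  back, so this parameterisation stays regular through the saddle-node
  bifurcation and is the one used for continuation.

A branch is continued from the initial-touch state (tangency of the
undeflected whisker, $F = 0$) by stepping $\theta_\mathrm{obj}$ in the
direction that produces a positive (pushing) contact force, with an
adaptive step (0.25° initial, capped at 2°, halved on failure). The
saddle-node fold is the extremum of the push angle along the branch; it
is detected on the grid and refined by golden-section search to 0.01°.
This extremum-based location was preferred to bisection on solver failure
because it does not rely on the failure behaviour of the Newton
iteration. Pull-off — the contact arclength reaching $L_w$ — is refined
by root-finding on $s_\mathrm{obj}(\theta_\mathrm{obj}) = L_w$.
Solutions with $s_\mathrm{obj} > L_w$ are returned but flagged
non-physical; for cylindrical whiskers the unstable partner solution is
typically of this kind.

The contact-point parameterisation on the circle covers one half of the
circle per sign convention, so a side flag (pole centre to the right or
left of the whisker tangent at contact) is carried through the solver;
it selects both the contact point and the force direction. Concave
backward (CB) contacts put the pole on the convex side of the intrinsic
curvature, concave forward (CF) on the concave side.

### Stability

The static solution connected to initial touch is stable; past the fold
the branch is unstable. Independently, of two coexisting solutions at the
same push angle, the one with the lower stored bending energy
$\int M_z^2/(2 E I)\, ds$ is the stable one (it bends less). The package
labels stability by branch position and cross-checks with the energy
criterion; disagreement yields `"unknown"`. A Hopf-type loss of stability
before the fold is not searched for; the quasi-static framework gives no
access to it, and the saddle-node scenario is the one the detachment
angles support.

## The push angle

The push angle $\theta_p$ measures how far the whisker has been rotated
into the object beyond initial touch, signed positive for CB and negative
for CF contacts. The package uses two operational definitions, which
agree near touch and differ by a few tenths of a degree at strong
deflection:

* **drive rotation** — $\theta_p = \theta_0^\mathrm{touch} - \theta_0$,
  the base rotation since exact tangency. This is what a galvo drive
  realises directly and what branches, detachment events and sweeps
  report. The tangency reference is computed by root-finding the base
  rotation at which the undeflected whisker touches the pole circle, so
  a supplied pose that slightly penetrates the pole (e.g. one specified
  with centimetre coordinates printed to two decimals) is anchored
  correctly.
* **virtual-contact construction** — an undeflected whisker is drawn at
  the current pose, the point on it at the same base-to-contact distance
  $d$ as the real contact is the virtual contact, and $\theta_p$ is the
  angle at the base between the rays to the real and virtual contacts
  (`push_angle()`). This is the estimator available for a single tracked
  video frame, and it is what the tracked-shape analysis uses.

The difference between the two arises because the contact point slides
along the pole and $d$ changes as the whisker is pushed; for the
worked-example conical whisker at its detachment angle it is about 0.45°.

## Tracked-shape analysis

Tracked whisker medial axes arrive as ordered point lists. The base angle
is estimated by an orthogonal line fit of the fifth through tenth points
from the base — the first few points are unreliable because of fur. That
fit estimates the tangent near the middle of the fitted span, roughly a
millimetre from the base, where the whisker has already turned by one to
two degrees (intrinsic curvature plus load-induced bending). The
push-angle extractor therefore measures the local curvature from the
track itself (a quadratic fit over points 3–20) and transfers the fitted
tangent back to the base before applying the virtual-contact
construction. The contact point is the best point of the first contiguous
run of tracked points within a gate (10 pixels) of the pole surface,
refined along the interpolated polyline — the first run, because the free
whisker segment beyond the contact also passes close to the pole.

The synthetic fixture generator samples model shapes (contact solution up
to $s_\mathrm{obj}$, undeflected continuation beyond) at a fixed number
of points equally spaced in arclength and adds seeded isotropic Gaussian
noise. It emulates the geometry of high-speed videography, not its
imaging physics: no whisker-width profile, no illumination gradients, no
tracking dropouts, and its noise is independent between points whereas
tracker errors are correlated along the whisker. Passing the recovery
tests therefore demonstrates the correctness of the geometric analysis
chain, not the performance of any particular tracker. Two noise scales
appear in the tests: one full pixel (0.031 mm) when exercising the
base-angle estimator alone on a 40-point track, and a quarter pixel when
testing end-to-end push-angle recovery on 120-point tracks — medial-axis
trackers average across the whisker's image profile and localise the
backbone to a fraction of a pixel, and at a full pixel of independent
per-point noise the five-point base fit simply does not carry one-degree
information, whatever the estimator.

Out-of-plane droop is handled only through the constant-elevation
projection correction $s_\mathrm{true} = s_\mathrm{proj}/\cos(\phi)$ (a
~3% effect at typical elevations); full three-dimensional bending and
torsion are out of scope. The effective whisker length — poorly defined
on video because the base is hidden in fur — is calibrated mechanically:
`calibrate_effective_length()` adjusts $L_w$ until the predicted slip-off
angle at the largest slip-off distance matches the observed one, a
one-dimensional root-find bracketed between the shortest length that
reaches the contact and roughly twice the contact distance.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `E_GPa` | 3 | GPa | Young's modulus of whisker keratin |
| `A_per_mm` | 0.02 | 1/mm | intrinsic parabola coefficient |
| `x_vertex_mm` | 0 | mm | parabola vertex offset (behaving-mouse fits use 2.2) |
| `shoot_tol` | 1e-9 | – | scaled boundary-residual tolerance |
| `ode_rtol` / `ode_atol` | 1e-9 / 1e-12 | – | integrator tolerances |
| `step_deg` | 0.25 | deg | initial continuation step in the contact angle |
| `fold_tol_deg` | 0.01 | deg | fold refinement tolerance |
| `penetration_tol` | 0.02 | of `r_pole` | accepted pose penetration at initial touch |
| `theta_p_max_deg` | 180 | deg | continuation cap; values beyond 90° are far outside whisking |

Angles are stored in radians internally and exposed in degrees; all other
internal computation is SI. Constructors take the units whisker work is
reported in (mm, µm, GPa, degrees), named in the argument.

## Detachment curves and pole placement

`detachment_curve()` maps the critical push angle over object distance
$d$ by placing, for each $d$, a pole tangent to the undeflected whisker
with base-to-contact distance $d$, on the CB or CF side, and locating the
detachment. This tangency-at-distance rule is a reconstruction: published
figures in this area print pole centres only for one distance, and those
centres are consistent with tangency only to within the rounding of the
printed coordinates. The critical angle is sensitive to placement at
roughly 4°/mm of $d$ for mid-shaft cylinder contacts, so bounds quoted
near a placement-sensitive threshold (for example "beyond 90°" for a
cylinder contacted at 10 mm, where this package computes 89.2°) should be
read with that uncertainty in mind. The scientific conclusion — that
cylindrical whiskers only slip far beyond the ~50° peak-to-peak whisking
envelope, while conical whiskers slip within it — is robust to the
placement rule.

## Sweep simulation

`simulate_sweep()` drives the base angle along a trajectory (sinusoidal
by default — galvo scanners are conventionally driven sinusoidally at low
frequency; a triangle wave is available) and solves the fixed-pose
problem per frame, seeded from the previous frame. Contact opens at
tangency (`touch_onset`, found by bisection between frames, so event
timing is independent of frame rate) and closes by `slip_off` (the
shooting solver stops converging because the fold was crossed; the event
angle is bisected between the last solvable and first unsolvable base
angle), `pull_off` ($s_\mathrm{obj}$ reaches $L_w$, root-found), or
`release` (the contact force crosses zero as the drive rotates back
through the touch angle). After a slip or pull the whisker is taken to
spring instantaneously to its free shape; frames in which that free
shape still overlaps the pole are flagged `passing` and no re-contact is
attempted until the overlap clears — immediate re-contact of a strongly
deflected whisker that has not yet cleared the pole is not modelled.

## Design choices made where the design was open

* The base angle for a configuration given as "parabola from the origin"
  is taken to be the parabola's base tangent; the pose is explicit
  everywhere else.
* Degenerate inputs: a cylindrical geometry has no virtual cone
  (`virtual_cone_length()` errors); arclengths outside $[0, L_w]$ are
  domain errors; a pole overlapping the whisker beyond 2% of its radius
  is rejected as a penetrating configuration; object distances beyond the
  whisker's reach are flagged `unreachable` in detachment curves rather
  than dropped.
* Ties and sign conventions: for a straight whisker (A = 0) the CB/CF
  labels follow the same right/left-of-tangent rule as a convention; the
  `"protraction"` sign convention for behaving-animal data (torsion
  decouples sign from intrinsic curvature) is an explicit switch, and no
  torsion model is guessed.
* Problem sizes in the shipped tests: continuation steps of 0.25–1°,
  10 random instances for the elastica cross-check (200-segment chains),
  synthetic sessions of 20–160 frames, and 40–1000 Monte-Carlo
  replicates per estimator check. These sizes were chosen so the full suite exercises
  every code path at meaningful accuracy in about two minutes.

## Known limitations

Planar, frictionless, quasi-static; point contact with a single pole;
no dynamics after detachment (the fast post-slip motion and texture
stick-slip are explicitly outside the model); no elliptical
cross-sections or along-length modulus gradients; no three-dimensional
droop or torsion beyond the constant-elevation projection correction.
The discrete-elastica relaxation used in the tests is an independent
cross-check of the solver, not a production solver: its penalty
formulation has a non-physical basin (chain end on the far side of the
pole) that is avoided by homotopy from the tangency pose.
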