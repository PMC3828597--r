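# vibrissa

Quasi-static mechanics of tapered whiskers contacting a cylindrical pole.

Rodent facial whiskers are thin, intrinsically curved, linearly tapered
elastic beams: truncated cones whose bending stiffness `E I(s)` drops by
about five orders of magnitude from base to tip. When such a whisker is
rotated against a pole it deflects, slides along the object, and
detaches in one of two qualitatively different ways: a **slip-off**, in
which the stable and unstable static solutions coalesce and annihilate
at a saddle-node bifurcation while the contact is still on the shaft
(`s_obj < L_w`), or a **pull-off**, forced when the whisker tip reaches
the contact point (`s_obj = L_w`). Conical whiskers slip off at push
angles within the natural whisking range; hypothetical cylindrical
whiskers of the same length only slip far beyond it and instead get
stuck until pulled off — a mechanical argument for why whisker taper
matters for active touch.

The package solves the planar large-deflection Euler–Bernoulli contact
problem as a boundary-value problem,

    dθ/ds = κ_i(s) + M_z(s) / (E I(s)),   dx/ds = cos θ,   dy/ds = sin θ,

rescaled by `σ = s / s_obj` onto `[0, 1]`, with the contact force `F`,
contact angle `θ_obj` and contact arclength `s_obj` as unknown constants
and boundary conditions at the base (pose) and at the contact point on
the pole circle (position and tangency). It is solved by iterative
shooting (adaptive Runge–Kutta integration with a compiled right-hand
side; damped Newton on the boundary residual), continued in the contact
angle through the saddle-node fold, and wrapped in higher-level tools:

* `solve_contact()` — one static solution (stable and unstable branches),
* `continue_branch()` / `find_detachment()` — branch continuation, fold
  (slip-off) and tip-release (pull-off) detection,
* `detachment_curve()` — critical push angle vs object distance, per
  contact side (concave backward / concave forward),
* `simulate_sweep()` — quasi-static galvo-style rotation sweeps with
  touch / slip / pull / release events,
* `estimate_base_angle()`, `extract_push_angle()`,
  `calibrate_effective_length()`, `generate_fixture()` — analysis of
  tracked whisker medial-axis points, with a seeded synthetic fixture
  generator so the chain is testable without video data.

## Worked example

A 20 mm conical whisker (base radius 30 µm, tip 1.5 µm, E = 3 GPa,
intrinsic parabola `y = 0.02 x²` in mm units) pushed concave-backward
into a 0.25 mm pole centred at (15.13, 4.29) mm:

```r
library(vibrissa)
geom <- whisker_geometry(20, 30, 1.5, E_GPa = 3, A_per_mm = 0.02)
pl   <- pole(0.25, 15.13, 4.29)
pose <- base_pose(0, 0, 0)

initial_touch(geom, pose, pl)
#> Contact point (CB): (15, 4.504) mm, s_obj = 15.86 mm, d = 15.66 mm, theta_obj = 30.98 deg

br <- continue_branch(geom, pose, pl)
summary(br)
#> Contact branch (CB): 232 points
#>   theta_p: [0.000, 15.599] deg; F up to 3.14 uN; s_obj up to 17.87 mm
#>   saddle-node fold after point 169
#> Detachment: slip_off at theta_p = 15.600 deg (d = 15.66 mm, s_obj = 17.43 mm)
```

The undeflected whisker first touches the pole 15.7 mm from the base
(the object distance `d`). Pushing it in, the contact force rises to a
few µN and the contact point slides outward until, at a push angle of
15.6°, the stable and unstable solutions merge and the whisker slips off
with the contact still 2.6 mm short of the tip. The same pole contacted
by a cylindrical "whisker" of equal length and base radius behaves
differently:

```r
cyl <- whisker_geometry(20, 30, 30, E_GPa = 3, A_per_mm = 0.02)
find_detachment(cyl, pose, pl)
#> Detachment: pull_off at theta_p = 62.753 deg (d = 15.66 mm, s_obj = 20 mm)
```

— no slip-off at all: contact persists until the tip is dragged to the
contact point at a push angle of 62.8°, far outside the ~50° peak-to-peak
whisking envelope.

A command-line front end over the same functions lives in
`inst/cli/vibrissa.R` (commands `solve`, `detach-curve`, `sweep`,
`fixtures`, `analyze`, `calibrate-length`), driven by a YAML run
configuration; see `inst/extdata/conical_run.yaml` for a template:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "vibrissa.R", package = "vibrissa"))') \
    detach-curve --config inst/extdata/conical_run.yaml --out out/
```

The methods vignette (`vignettes/whisker-mechanics.Rmd`) documents the
model, the shooting/continuation numerics, the push-angle conventions,
and the synthetic-fixture assumptions.

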