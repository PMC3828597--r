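#' Whisker morphology and material
#'
#' Describes one whisker as a truncated cone (or a cylinder) of length
#' `L_w` with base radius `r_base`, tip radius `r_tip` and Young's modulus
#' `E`. The undeflected (intrinsic) shape is the parabola
#' `y = A (x - x_vertex)^2` in whisker-local coordinates, traversed from the
#' base at local `x = 0`. All fields are stored in SI units; arguments carry
#' their unit in the name.
#'
#' @param L_w_mm truncated whisker length, mm.
#' @param r_base_um base radius, micrometres.
#' @param r_tip_um tip radius, micrometres. Equal to `r_base_um` for a
#'   cylindrical whisker, smaller for a cone.
#' @param E_GPa Young's modulus, GPa. Whisker keratin is close to 3 GPa.
#' @param A_per_mm coefficient of the intrinsic parabola, 1/mm. Zero gives a
#'   straight whisker.
#' @param x_vertex_mm offset of the parabola vertex along the whisker's own
#'   x-axis, mm (0 puts the vertex at the base).
#' @return An object of class `whisker_geometry` with SI fields `L_w`,
#'   `r_base`, `r_tip`, `E`, `A`, `x_vertex`, `shape_kind`
#'   (`"conical"`/`"cylindrical"`) and, for cones, the virtual full-cone
#'   length `L`.
#' @examples
#' geom <- whisker_geometry(20, 30, 1.5, E_GPa = 3, A_per_mm = 0.02)
#' geom
#' @export
whisker_geometry <- function(L_w_mm, r_base_um, r_tip_um = r_base_um,
                             E_GPa = 3, A_per_mm = 0, x_vertex_mm = 0) {
  L_w <- L_w_mm * 1e-3
  r_base <- r_base_um * 1e-6
  r_tip <- r_tip_um * 1e-6
  if (!is.finite(L_w) || L_w <= 0) stop("L_w must be positive")
  if (r_tip < 0 || r_base <= 0 || r_tip > r_base)
    stop("radii must satisfy 0 <= r_tip <= r_base, r_base > 0")
  if (E_GPa <= 0) stop("Young's modulus must be positive")
  if (A_per_mm < 0) stop("A must be non-negative")
  cylindrical <- (r_base - r_tip) <= 1e-9 * r_base
  g <- list(L_w = L_w, r_base = r_base, r_tip = r_tip,
            E = E_GPa * 1e9, A = A_per_mm * 1e3,
            x_vertex = x_vertex_mm * 1e-3,
            shape_kind = if (cylindrical) "cylindrical" else "conical")
  g$L <- if (cylindrical) NA_real_ else L_w * r_base / (r_base - r_tip)
  class(g) <- "whisker_geometry"
  g
}

#' @export
print.whisker_geometry <- function(x, ...) {
  cat(sprintf("Whisker (%s): L_w = %.4g mm, r_base = %.4g um, r_tip = %.4g um\n",
              x$shape_kind, x$L_w * 1e3, x$r_base * 1e6, x$r_tip * 1e6))
  cat(sprintf("  E = %.4g GPa, intrinsic parabola A = %.4g 1/mm, vertex at %.4g mm\n",
              x$E / 1e9, x$A / 1e3, x$x_vertex * 1e3))
  if (x$shape_kind == "conical")
    cat(sprintf("  virtual full-cone length L = %.6g mm\n", x$L * 1e3))
  invisible(x)
}

#' Base pose of the whisker
#'
#' Position of the whisker base and the angle of the base tangent with the
#' world x-axis.
#'
#' @param x_mm,y_mm base position, mm.
#' @param theta0_deg base angle vs the x-axis, degrees.
#' @return An object of class `base_pose` with SI fields `x0`, `y0` (m) and
#'   `theta0` (radians).
#' @export
base_pose <- function(x_mm = 0, y_mm = 0, theta0_deg = 0) {
  if (!is.finite(theta0_deg)) stop("theta0 must be finite")
  structure(list(x0 = x_mm * 1e-3, y0 = y_mm * 1e-3,
                 theta0 = deg2rad(theta0_deg)),
            class = "base_pose")
}

#' @export
print.base_pose <- function(x, ...) {
  cat(sprintf("Base pose: (%.4g, %.4g) mm, theta0 = %.4g deg\n",
              x$x0 * 1e3, x$y0 * 1e3, rad2deg(x$theta0)))
  invisible(x)
}

#' Cylindrical pole
#'
#' The contacted object: a cylindrical pole perpendicular to the plane of
#' whisker motion, seen as a circle of radius `r_pole`.
#'
#' @param r_mm pole radius, mm.
#' @param x_mm,y_mm pole centre, mm.
#' @return An object of class `pole` with SI fields `r_pole`, `x_cen`,
#'   `y_cen`.
#' @export
pole <- function(r_mm, x_mm, y_mm) {
  if (r_mm <= 0) stop("pole radius must be positive")
  structure(list(r_pole = r_mm * 1e-3, x_cen = x_mm * 1e-3,
                 y_cen = y_mm * 1e-3), class = "pole")
}

#' @export
print.pole <- function(x, ...) {
  cat(sprintf("Pole: r = %.4g mm at (%.4g, %.4g) mm\n",
              x$r_pole * 1e3, x$x_cen * 1e3, x$y_cen * 1e3))
  invisible(x)
}

#' Virtual full-cone length
#'
#' A truncated cone is virtually extended to a perfect cone; its length `L`
#' satisfies `r_w(s) = (L - s) r_base / L`, so `L = L_w r_base /
#' (r_base - r_tip)`.
#'
#' @param geom a [whisker_geometry()].
#' @return Virtual cone length in metres.
#' @export
virtual_cone_length <- function(geom) {
  stopifnot(inherits(geom, "whisker_geometry"))
  if (geom$shape_kind == "cylindrical")
    stop("cylindrical whisker has no virtual cone")
  geom$L
}

#' Whisker radius at an arclength
#'
#' Linear taper: `r_w(s) = (L - s) r_base / L` for a cone, constant
#' `r_base` for a cylinder.
#'
#' @param geom a [whisker_geometry()].
#' @param s arclength from the base, metres; vectorized. Must lie in
#'   `[0, L_w]`.
#' @return Radius in metres.
#' @export
radius_at <- function(geom, s) {
  stopifnot(inherits(geom, "whisker_geometry"))
  if (any(s < -1e-12 | s > geom$L_w * (1 + 1e-12)))
    stop("arclength outside [0, L_w]")
  if (geom$shape_kind == "cylindrical") rep(geom$r_base, length(s))
  else (geom$L - s) * geom$r_base / geom$L
}

#' Area moment of inertia at an arclength
#'
#' Circular cross-section: `I(s) = pi r_w(s)^4 / 4`. The bending stiffness
#' is `E I(s)`; for a strongly tapered whisker it drops by about five orders
#' of magnitude from base to tip.
#'
#' @inheritParams radius_at
#' @return Second moment of area in m^4.
#' @export
area_moment_at <- function(geom, s) {
  r <- radius_at(geom, s)
  pi * r^4 / 4
}

#' Intrinsic (undeflected) curvature at an arclength
#'
#' Signed curvature of the intrinsic parabola at arclength `s` from the
#' base; positive curvature turns the tangent counterclockwise. At the
#' vertex the magnitude is `2 A`, and it decreases monotonically with
#' distance from the vertex.
#'
#' @inheritParams radius_at
#' @return Curvature in 1/m (vectorized over `s`).
#' @export
intrinsic_curvature <- function(geom, s) {
  stopifnot(inherits(geom, "whisker_geometry"))
  parab_kappa_s(s, geom$A, geom$x_vertex)
}

#' Discretized undeflected whisker shape
#'
#' Samples the intrinsic parabola at `n` points equally spaced in arclength
#' and maps them rigidly to the base pose (translation to the base point,
#' rotation so the base tangent equals `theta0`).
#'
#' @inheritParams radius_at
#' @param pose a [base_pose()].
#' @param n number of sample points (>= 2).
#' @return A data frame with columns `s`, `x`, `y`, `theta` (SI units,
#'   radians); the polyline arclength equals `L_w` to within `1e-6 L_w`.
#' @export
undeflected_shape <- function(geom, pose, n = 200) {
  stopifnot(inherits(geom, "whisker_geometry"), inherits(pose, "base_pose"))
  if (n < 2) stop("n must be at least 2")
  s <- seq(0, geom$L_w, length.out = n)
  p <- undeflected_point(s, geom, pose)
  data.frame(s = s, x = p$x, y = p$y, theta = p$theta)
}

# distance from the pole centre to the undeflected whisker at a rotation phi
# of the base pose, minimised over arclength; returns the minimising s too
pole_gap <- function(geom, pose, pole, phi = 0) {
  rot <- base_pose()
  rot$x0 <- pose$x0; rot$y0 <- pose$y0; rot$theta0 <- pose$theta0 + phi
  dist_at <- function(s) {
    p <- undeflected_point(s, geom, rot)
    sqrt((p$x - pole$x_cen)^2 + (p$y - pole$y_cen)^2)
  }
  # coarse scan, then local refinement
  s_grid <- seq(0, geom$L_w, length.out = 257)
  d_grid <- dist_at(s_grid)
  i <- which.min(d_grid)
  lo <- s_grid[max(1, i - 1)]; hi <- s_grid[min(length(s_grid), i + 1)]
  op <- stats::optimize(dist_at, c(lo, hi), tol = 1e-13)
  list(s = op$minimum, dist = op$objective,
       gap = op$objective - pole$r_pole, pose = rot)
}

#' Initial tangent contact of the undeflected whisker with the pole
#'
#' Finds the rotation of the base pose (about the base point) at which the
#' undeflected whisker is exactly tangent to the pole circle. That pose
#' defines the angle of initial touch, the zero reference for the push
#' angle. A supplied pose that already touches within a small penetration
#' tolerance is accepted and only nudged to exact tangency; a pole that
#' overlaps the whisker more deeply is rejected, as is a pole the whisker
#' cannot reach at any rotation.
#'
#' @inheritParams undeflected_shape
#' @param pole a [pole()].
#' @param penetration_tol accepted penetration of the supplied pose,
#'   as a fraction of the pole radius.
#' @return An object of class `contact_point`: list with `x_obj`, `y_obj`,
#'   `theta_obj` (radians), `s_obj`, `d` (m), `theta0_touch` (radians, the
#'   base angle at exact tangency) and `side` (`"CB"`/`"CF"`, which side of
#'   the whisker the pole sits on).
#' @export
initial_touch <- function(geom, pose, pole, penetration_tol = 0.02) {
  stopifnot(inherits(geom, "whisker_geometry"), inherits(pose, "base_pose"),
            inherits(pole, "pole"))
  g0 <- pole_gap(geom, pose, pole)
  if (g0$gap < -penetration_tol * pole$r_pole)
    stop("penetrating configuration: pole overlaps the undeflected whisker")

  # rotate the base until the minimal distance equals r_pole
  gap_fn <- function(phi) pole_gap(geom, pose, pole, phi)$gap
  phi_star <- NA_real_
  if (abs(g0$gap) <= penetration_tol * pole$r_pole) {
    # already tangent to within tolerance: refine the rotation root nearest 0
    for (w in c(0.002, 0.01, 0.05)) {
      if (gap_fn(-w) * gap_fn(w) < 0) {
        phi_star <- stats::uniroot(gap_fn, c(-w, w), tol = 1e-12)$root
        break
      }
      if (abs(gap_fn(0)) < 1e-12 * geom$L_w) { phi_star <- 0; break }
    }
    if (is.na(phi_star)) phi_star <- 0
  } else {
    # not touching: search both rotation senses for the nearest tangency
    roots <- c()
    for (sgn in c(-1, 1)) {
      lo <- 0
      for (w in seq(0.02, pi, by = 0.02)) {
        if (gap_fn(0) * gap_fn(sgn * w) < 0) {
          r <- stats::uniroot(gap_fn, sort(c(sgn * lo, sgn * w)), tol = 1e-12)$root
          roots <- c(roots, r)
          break
        }
        lo <- w
      }
    }
    if (length(roots) == 0)
      stop("no contact: pole unreachable by the undeflected whisker")
    phi_star <- roots[which.min(abs(roots))]
  }

  gt <- pole_gap(geom, pose, pole, phi_star)
  p <- undeflected_point(gt$s, geom, gt$pose)
  d <- sqrt((p$x - pose$x0)^2 + (p$y - pose$y0)^2)
  # side of the whisker the pole centre is on: cross product of the local
  # tangent with the contact->centre vector; CB puts the pole on the convex
  # side of the intrinsic curvature
  cz <- cos(p$theta) * (pole$y_cen - p$y) - sin(p$theta) * (pole$x_cen - p$x)
  # A >= 0 by construction, so the convex side is to the right of the
  # tangent; a straight whisker keeps the same labelling as a convention
  side <- if (cz < 0) "CB" else "CF"
  structure(list(x_obj = p$x, y_obj = p$y, theta_obj = p$theta,
                 s_obj = gt$s, d = d, theta0_touch = gt$pose$theta0,
                 side = side),
            class = "contact_point")
}

#' @export
print.contact_point <- function(x, ...) {
  cat(sprintf(
    "Contact point (%s): (%.4g, %.4g) mm, s_obj = %.4g mm, d = %.4g mm, theta_obj = %.4g deg\n",
    x$side, x$x_obj * 1e3, x$y_obj * 1e3, x$s_obj * 1e3, x$d * 1e3,
    rad2deg(x$theta_obj)))
  invisible(x)
}

#' Push angle from the virtual-contact construction
#'
#' The push angle measures how far the whisker has been rotated into the
#' object beyond initial touch. Given a deflected whisker with base pose
#' `pose` contacting the object at `contact`, an undeflected whisker is
#' drawn at the same pose and the point on it at the same Euclidean
#' distance `d` from the base is taken as the virtual contact. The push
#' angle is the signed angle at the base between the rays towards the real
#' and the virtual contact points: positive for concave-backward (CB)
#' contacts, negative for concave-forward (CF).
#'
#' For a whisker driven by pure base rotation this construction recovers
#' the rotation since touch to within a few tenths of a degree; branch and
#' sweep results report the rotation itself, while this estimator is what
#' tracked single frames afford.
#'
#' @param pose the [base_pose()] of the deflected whisker.
#' @param contact either a `contact_point` or a list/vector with fields
#'   `x_obj`, `y_obj` (m).
#' @param geom a [whisker_geometry()].
#' @return Signed push angle in degrees.
#' @export
push_angle <- function(pose, contact, geom) {
  stopifnot(inherits(pose, "base_pose"), inherits(geom, "whisker_geometry"))
  xo <- contact$x_obj; yo <- contact$y_obj
  d <- sqrt((xo - pose$x0)^2 + (yo - pose$y0)^2)
  chord <- function(s) {
    p <- undeflected_point(s, geom, pose)
    sqrt((p$x - pose$x0)^2 + (p$y - pose$y0)^2) - d
  }
  hi <- geom$L_w
  if (chord(hi) < 0)
    stop("virtual point not found: d exceeds the undeflected whisker's reach")
  s_virtual <- stats::uniroot(chord, c(1e-9 * geom$L_w, hi), tol = 1e-13)$root
  pv <- undeflected_point(s_virtual, geom, pose)
  vr <- c(xo - pose$x0, yo - pose$y0)
  vv <- c(pv$x - pose$x0, pv$y - pose$y0)
  # with A >= 0 a counterclockwise offset of the real contact relative to
  # the virtual contact is a concave-backward deflection, hence positive
  delta <- atan2(vv[1] * vr[2] - vv[2] * vr[1], sum(vv * vr))
  rad2deg(delta)
}
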