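# Internal helpers for the undeflected (intrinsic) whisker shape: a parabola
# y' = A (x' - x_vertex)^2 in whisker-local coordinates, traversed by
# arclength from the base at local x' = 0. Mirrors the closed forms used in
# the compiled right-hand side so R-level geometry and the integrator agree.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# arclength from local x' = 0 to x' = x along y' = A (x' - xv)^2
parab_arclen <- function(x, A, xv = 0) {
  if (abs(A) < 1e-12) return(x)
  u0 <- -2 * A * xv
  u1 <- 2 * A * (x - xv)
  S <- function(u) u * sqrt(1 + u^2) + asinh(u)
  (S(u1) - S(u0)) / (4 * A)
}

# invert the (monotone) arclength map; vectorized over s
parab_x_of_s <- function(s, A, xv = 0) {
  if (abs(A) < 1e-12) return(s)
  vapply(s, function(si) {
    x <- si
    for (i in 1:100) {
      u <- 2 * A * (x - xv)
      f <- parab_arclen(x, A, xv) - si
      x <- x - f / sqrt(1 + u^2)
      if (abs(f) < 1e-15 + 1e-13 * abs(si)) break
    }
    x
  }, numeric(1))
}

# signed curvature at arclength s (positive: tangent rotates counterclockwise)
parab_kappa_s <- function(s, A, xv = 0) {
  if (abs(A) < 1e-12) return(rep(0, length(s)))
  x <- parab_x_of_s(s, A, xv)
  u <- 2 * A * (x - xv)
  2 * A / (1 + u^2)^1.5
}

# local coordinates and tangent angle at arclength s (base at origin,
# base tangent NOT normalised: the local tangent at s = 0 is
# atan(2 A (0 - xv)))
parab_point_s <- function(s, A, xv = 0) {
  x <- parab_x_of_s(s, A, xv)
  list(x = x, y = A * (x - xv)^2 - A * xv^2, theta = atan(2 * A * (x - xv)))
}

# base tangent angle of the local parabola
parab_theta_base <- function(A, xv = 0) atan(2 * A * (0 - xv))

# map local coordinates to world coordinates for a base pose: translate the
# base to (x0, y0) and rotate so the local base tangent points at theta0
local_to_world <- function(xl, yl, pose, A, xv = 0) {
  phi <- pose$theta0 - parab_theta_base(A, xv)
  list(x = pose$x0 + cos(phi) * xl - sin(phi) * yl,
       y = pose$y0 + sin(phi) * xl + cos(phi) * yl)
}

# world position and tangent angle of the undeflected whisker at arclength s
undeflected_point <- function(s, geom, pose) {
  p <- parab_point_s(s, geom$A, geom$x_vertex)
  w <- local_to_world(p$x, p$y, pose, geom$A, geom$x_vertex)
  phi <- pose$theta0 - parab_theta_base(geom$A, geom$x_vertex)
  list(x = w$x, y = w$y, theta = p$theta + phi)
}
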