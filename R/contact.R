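#' Solver settings for the shooting method
#'
#' Tolerances and controls for the iterative shooting solver and the branch
#' continuation built on it. Residuals are nondimensionalised (positions by
#' `L_w`, angles in radians) before comparison with `shoot_tol`.
#'
#' @param shoot_tol convergence tolerance on the scaled boundary residual.
#' @param max_iter Newton iteration cap per solve.
#' @param ode_rtol,ode_atol relative/absolute tolerance of the adaptive
#'   Runge-Kutta integrator.
#' @param n_output number of `sigma` samples on a returned solution curve.
#' @param step_deg initial continuation step in the contact angle, degrees.
#' @param step_min_deg,step_max_deg bounds of the adaptive step.
#' @param fold_tol_deg tolerance for locating a saddle-node fold, degrees.
#' @param theta_p_max_deg continuation cap on the push angle magnitude.
#' @param seed_strategy `"continuation"` (seed each solve from the previous
#'   branch point, starting at the initial-touch state) or `"cold_start"`
#'   (caller supplies a guess).
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(shoot_tol = 1e-9, max_iter = 25,
                            ode_rtol = 1e-9, ode_atol = 1e-12,
                            n_output = 201,
                            step_deg = 0.25, step_min_deg = 1e-3,
                            step_max_deg = 2, fold_tol_deg = 0.01,
                            theta_p_max_deg = 180,
                            seed_strategy = c("continuation", "cold_start")) {
  stopifnot(shoot_tol > 0, ode_rtol > 0, ode_atol > 0, max_iter >= 1)
  structure(list(shoot_tol = shoot_tol, max_iter = max_iter,
                 ode_rtol = ode_rtol, ode_atol = ode_atol,
                 n_output = n_output, step_deg = step_deg,
                 step_min_deg = step_min_deg, step_max_deg = step_max_deg,
                 fold_tol_deg = fold_tol_deg,
                 theta_p_max_deg = theta_p_max_deg,
                 seed_strategy = match.arg(seed_strategy)),
            class = "solver_settings")
}

ws_parms <- function(geom, pole, side = 1) {
  c(pole$x_cen, pole$y_cen, pole$r_pole, geom$E, geom$A, geom$x_vertex,
    as.numeric(geom$shape_kind == "conical"),
    if (geom$shape_kind == "conical") geom$L else 1,
    geom$r_base, side)
}

# contact point on the pole circle for a contact angle and side
ws_contact_xy <- function(pole, theta_obj, side = 1) {
  c(x = pole$x_cen - side * pole$r_pole * sin(theta_obj),
    y = pole$y_cen + side * pole$r_pole * cos(theta_obj))
}

# integrate the shooting system from sigma = 0 with given base pose and
# unknown constants; returns either the endpoint or the full curve
ws_integrate <- function(geom, pole, x0, y0, theta0, F, theta_obj, s_obj,
                         settings, sigma = c(0, 1), side = 1) {
  y <- c(x = x0, y = y0, theta = theta0, F = F,
         theta_obj = theta_obj, s_obj = s_obj)
  # a wildly wrong shooting guess can make the integrand effectively
  # stiff; the integrator then stops early, which the callers detect via
  # the final time rather than via console warnings
  out <- suppressWarnings(
    deSolve::ode(y = y, times = sigma, func = "whisker_derivs",
                 parms = ws_parms(geom, pole, side), dllname = "vibrissa",
                 initfunc = "whisker_init", method = "ode45",
                 rtol = settings$ode_rtol, atol = settings$ode_atol))
  out
}

# raw boundary residual (m, m, rad): endpoint against the contact-point
# conditions on the pole circle
ws_residual_raw <- function(end, pole, side = 1) {
  th <- end[["theta_obj"]]
  xy <- ws_contact_xy(pole, th, side)
  c(end[["x"]] - xy[["x"]], end[["y"]] - xy[["y"]], end[["theta"]] - th)
}

# damped Newton with finite-difference Jacobian on a 3-vector residual;
# the Jacobian can be recycled between calls (chord iterations) which cuts
# most of the integrations during continuation
ws_newton <- function(resid_fn, u, scales, settings, J = NULL) {
  r <- resid_fn(u)
  if (any(!is.finite(r))) return(list(converged = FALSE, u = u, J = NULL))
  best <- max(abs(r))
  fresh <- FALSE
  for (it in seq_len(settings$max_iter)) {
    if (best < settings$shoot_tol)
      return(list(converged = TRUE, u = u, J = J, residual = r, iters = it - 1))
    if (is.null(J)) {
      J <- matrix(0, 3, 3)
      for (j in 1:3) {
        du <- numeric(3); du[j] <- scales[j]
        rj <- resid_fn(u + du)
        if (any(!is.finite(rj))) return(list(converged = FALSE, u = u, J = NULL))
        J[, j] <- (rj - r) / scales[j]
      }
      fresh <- TRUE
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE, u = u, J = NULL))
    lam <- 1
    repeat {
      r_new <- resid_fn(u - lam * step)
      ok <- all(is.finite(r_new)) && max(abs(r_new)) < best
      if (ok || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (!ok) {
      if (!fresh) { J <- NULL; next }   # recycled Jacobian went stale: rebuild
      return(list(converged = FALSE, u = u, J = NULL))
    }
    u <- u - lam * step
    r <- r_new
    fresh <- FALSE
    # poor contraction or damping signals the recycled Jacobian drifted
    if (lam < 1 || max(abs(r)) > 0.5 * best) J <- NULL
    best <- max(abs(r))
  }
  list(converged = best < settings$shoot_tol, u = u, J = J, residual = r,
       iters = settings$max_iter)
}

# characteristic force for nondimensionalising the Newton steps
ws_force_scale <- function(geom) {
  geom$E * pi * geom$r_base^4 / 4 / geom$L_w^2
}

# one shooting solve. mode "pose": base angle fixed, unknowns
# (F, theta_obj, s_obj); mode "theta_obj": contact angle prescribed,
# unknowns (F, s_obj, theta0) - the parameterisation used for branch
# continuation, which stays regular through the saddle-node fold.
ws_solve <- function(geom, pose, pole, mode, guess, settings, J = NULL,
                     side = 1) {
  Fs <- ws_force_scale(geom)
  Ls <- geom$L_w
  endpoint <- function(theta0, F, theta_obj, s_obj) {
    out <- ws_integrate(geom, pole, pose$x0, pose$y0, theta0, F, theta_obj,
                        s_obj, settings, side = side)
    end <- out[nrow(out), ]
    if (!is.finite(end[["time"]]) || end[["time"]] < 1 - 1e-9)
      end[c("x", "y", "theta")] <- NA_real_
    end
  }
  scale_resid <- function(r) c(r[1] / Ls, r[2] / Ls, r[3])
  if (mode == "pose") {
    resid_fn <- function(u) {
      end <- endpoint(pose$theta0, u[1] * Fs, u[2], u[3] * Ls)
      scale_resid(ws_residual_raw(end, pole, side))
    }
    u0 <- c(guess$F / Fs, guess$theta_obj, guess$s_obj / Ls)
  } else {
    resid_fn <- function(u) {
      end <- endpoint(u[3], u[1] * Fs, guess$theta_obj, u[2] * Ls)
      scale_resid(ws_residual_raw(end, pole, side))
    }
    u0 <- c(guess$F / Fs, guess$s_obj / Ls, guess$theta0)
  }
  scales <- c(1e-6, 1e-6, 1e-6)
  ns <- ws_newton(resid_fn, u0, scales, settings, J = J)
  if (!ns$converged)
    return(list(converged = FALSE, J = ns$J))
  if (mode == "pose") {
    out <- list(converged = TRUE, theta0 = pose$theta0, F = ns$u[1] * Fs,
                theta_obj = ns$u[2], s_obj = ns$u[3] * Ls)
  } else {
    out <- list(converged = TRUE, theta0 = ns$u[3], F = ns$u[1] * Fs,
                theta_obj = guess$theta_obj, s_obj = ns$u[2] * Ls)
  }
  out$residual <- ns$residual
  out$J <- ns$J
  out$iters <- ns$iters
  out
}

# build the full classed solution object from converged unknowns
ws_solution <- function(geom, pose, pole, theta0, F, theta_obj, s_obj,
                        settings, stability = "unknown", side = 1) {
  sig <- seq(0, 1, length.out = settings$n_output)
  out <- ws_integrate(geom, pole, pose$x0, pose$y0, theta0, F, theta_obj,
                      s_obj, settings, sigma = sig, side = side)
  curve <- data.frame(sigma = out[, "time"], s = out[, "time"] * s_obj,
                      x = out[, "x"], y = out[, "y"], theta = out[, "theta"])
  xy <- ws_contact_xy(pole, theta_obj, side)
  xo <- xy[["x"]]; yo <- xy[["y"]]
  curve$M_z <- side * F * ((xo - curve$x) * cos(theta_obj) +
                           (yo - curve$y) * sin(theta_obj))
  EI <- geom$E * area_moment_at(geom, pmin(curve$s, geom$L_w))
  # stored elastic (bending) energy of the deflection, trapezoidal rule
  integrand <- curve$M_z^2 / (2 * EI)
  energy <- sum(diff(curve$s) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  res <- ws_residual_raw(out[nrow(out), ], pole, side)
  structure(list(
    curve = curve, F = F, side = side,
    F_vec = side * c(Fx = -F * sin(theta_obj), Fy = F * cos(theta_obj)),
    theta_obj = theta_obj, s_obj = s_obj, theta0 = theta0,
    d = sqrt((xo - pose$x0)^2 + (yo - pose$y0)^2),
    contact = c(x_obj = xo, y_obj = yo),
    energy = energy,
    residual = c(res[1] / geom$L_w, res[2] / geom$L_w, res[3]),
    physical = s_obj <= geom$L_w * (1 + 1e-9),
    stability = stability,
    geom = geom, pose = pose, pole = pole, settings = settings),
    class = "whisker_contact")
}

#' Solve the static whisker-pole contact problem by shooting
#'
#' Integrates the contact boundary-value problem from the whisker base and
#' adjusts the unknown constants until the far end meets the pole circle
#' tangentially. Two parameterisations are available: with `fixed =
#' "pose"` the base angle is prescribed and the unknowns are the force, the
#' contact angle and the contact arclength (two solutions, one stable and
#' one unstable, typically coexist); with `fixed = "theta_obj"` the contact
#' angle is prescribed and the base angle joins the unknowns, which is the
#' regular parameterisation along a solution branch.
#'
#' @inheritParams initial_touch
#' @param guess named list with starting values `F` (N), `theta_obj`
#'   (radians), `s_obj` (m) (and `theta0` for `fixed = "theta_obj"`). When
#'   omitted, the solver seeds itself from [initial_touch()], which is only
#'   adequate close to the barely-touching state.
#' @param settings a [solver_settings()].
#' @param fixed which quantity is prescribed; see Details.
#' @param side which side of the pole the whisker presses on: `+1` when
#'   the pole centre lies to the right of the whisker tangent at contact
#'   (concave-backward contacts for a whisker curving counterclockwise),
#'   `-1` for the other side. `NULL` derives it from [initial_touch()].
#' @return An object of class `whisker_contact`: the discretized curve
#'   (`sigma`, `s`, `x`, `y`, `theta`, `M_z`), contact force `F` and vector
#'   `F_vec`, `theta_obj`, `s_obj`, `theta0`, base-contact distance `d`,
#'   stored bending `energy`, the scaled boundary `residual`, a `physical`
#'   flag (`s_obj <= L_w`) and a `stability` label.
#' @export
solve_contact <- function(geom, pose, pole, guess = NULL,
                          settings = solver_settings(),
                          fixed = c("pose", "theta_obj"), side = NULL) {
  fixed <- match.arg(fixed)
  if (is.null(guess) || is.null(side)) {
    it <- initial_touch(geom, pose, pole)
    if (is.null(side)) side <- if (it$side == "CB") 1 else -1
    if (is.null(guess))
      guess <- list(F = 0, theta_obj = it$theta_obj, s_obj = it$s_obj,
                    theta0 = it$theta0_touch)
  }
  if (is.null(guess$theta0)) guess$theta0 <- pose$theta0
  sol <- ws_solve(geom, pose, pole, fixed, guess, settings, side = side)
  if (!sol$converged)
    ws_stop("shooting failed: no convergence from the supplied seed",
            "vibrissa_solver_failure")
  out <- ws_solution(geom, pose, pole, sol$theta0, sol$F, sol$theta_obj,
                     sol$s_obj, settings, side = side)
  if (!out$physical)
    warning("converged solution has s_obj > L_w and is not physical")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boundary residual of a candidate contact solution
#'
#' The three components of the shooting objective: the gap between the
#' integrated endpoint and the contact point on the pole circle (x and y,
#' scaled by `L_w`) and the mismatch between the endpoint tangent angle and
#' the contact angle (radians).
#'
#' @param candidate a `whisker_contact`.
#' @param geom,pole optionally override the stored geometry/pole.
#' @return Numeric length-3 vector.
#' @export
boundary_residual <- function(candidate, geom = candidate$geom,
                              pole = candidate$pole) {
  end <- c(x = candidate$curve$x[nrow(candidate$curve)],
           y = candidate$curve$y[nrow(candidate$curve)],
           theta = candidate$curve$theta[nrow(candidate$curve)],
           theta_obj = candidate$theta_obj)
  r <- ws_residual_raw(end, pole, candidate$side %||% 1)
  c(r[1] / geom$L_w, r[2] / geom$L_w, r[3])
}

#' @export
residuals.whisker_contact <- function(object, ...) boundary_residual(object)

#' @export
print.whisker_contact <- function(x, ...) {
  cat(sprintf("Whisker contact solution (%s%s)\n",
              x$stability, if (x$physical) "" else ", non-physical"))
  cat(sprintf("  F = %.4g uN at theta_obj = %.4g deg, s_obj = %.4g mm, d = %.4g mm\n",
              x$F * 1e6, rad2deg(x$theta_obj), x$s_obj * 1e3, x$d * 1e3))
  cat(sprintf("  base angle %.4g deg, bending energy %.4g nJ, |residual| = %.2g\n",
              rad2deg(x$theta0), x$energy * 1e9, max(abs(x$residual))))
  invisible(x)
}

#' @export
plot.whisker_contact <- function(x, add = FALSE, col = "black", lty = 1, ...) {
  cv <- x$curve
  if (!add) {
    plot(cv$x * 1e3, cv$y * 1e3, type = "l", asp = 1, col = col, lty = lty,
         xlab = "x (mm)", ylab = "y (mm)", ...)
    ang <- seq(0, 2 * pi, length.out = 100)
    lines(x$pole$x_cen * 1e3 + x$pole$r_pole * 1e3 * cos(ang),
          x$pole$y_cen * 1e3 + x$pole$r_pole * 1e3 * sin(ang), col = "grey40")
  } else {
    lines(cv$x * 1e3, cv$y * 1e3, col = col, lty = lty, ...)
  }
  invisible(x)
}

#' Label the stability of a contact solution
#'
#' Along a continued branch the segment connected to the initial-touch
#' state (before the saddle-node fold) is stable; the segment past the fold
#' is unstable. Independently, of two solutions coexisting at the same push
#' angle the one with the lower stored bending energy is the stable one.
#' Both criteria are evaluated when a branch context is supplied; if they
#' disagree the label is `"unknown"`.
#'
#' @param solution a `whisker_contact`.
#' @param branch_context optionally, the `whisker_branch` the solution was
#'   drawn from.
#' @return `"stable"`, `"unstable"` or `"unknown"`.
#' @export
classify_stability <- function(solution, branch_context = NULL) {
  if (is.null(branch_context)) return(solution$stability)
  br <- branch_context$points
  i_fold <- branch_context$fold_index
  # position on the branch: nearest point in (theta_obj, s_obj)
  i <- which.min((deg2rad(br$theta_obj_deg) - solution$theta_obj)^2 +
                 ((br$s_obj - solution$s_obj) / branch_context$geom$L_w)^2)
  by_fold <- if (is.na(i_fold) || i <= i_fold) "stable" else "unstable"
  # energy criterion: compare with the energy of the opposite sub-branch
  # interpolated at the same push angle (only defined when a fold exists)
  if (is.na(i_fold)) return(by_fold)
  other <- if (i <= i_fold) br[-seq_len(i_fold), ] else br[seq_len(i_fold), ]
  other <- other[is.finite(other$energy), , drop = FALSE]
  if (nrow(other) < 2) return(by_fold)
  tp <- br$theta_p_deg[i]
  if (min(other$theta_p_deg) - 1e-9 <= tp &&
      tp <= max(other$theta_p_deg) + 1e-9) {
    e_other <- stats::approx(other$theta_p_deg, other$energy, xout = tp,
                             rule = 2)$y
    by_energy <- if (br$energy[i] <= e_other) "stable" else "unstable"
    if (by_energy != by_fold) return("unknown")
  }
  by_fold
}

#' @export
summary.whisker_contact <- function(object, ...) {
  cat("Static whisker-pole contact solution\n")
  print(object$geom)
  cat(sprintf("  stability: %s%s\n", object$stability,
              if (object$physical) "" else " (non-physical: s_obj > L_w)"))
  cat(sprintf("  F = %.4g uN  (Fx, Fy) = (%.4g, %.4g) uN\n",
              object$F * 1e6, object$F_vec[1] * 1e6, object$F_vec[2] * 1e6))
  cat(sprintf("  theta_obj = %.4g deg, s_obj = %.4g mm, d = %.4g mm\n",
              rad2deg(object$theta_obj), object$s_obj * 1e3, object$d * 1e3))
  cat(sprintf("  bending energy = %.4g nJ, max |residual| = %.2g\n",
              object$energy * 1e9, max(abs(object$residual))))
  invisible(object)
}
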