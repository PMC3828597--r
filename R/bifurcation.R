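# Branch continuation in the contact angle, saddle-node (slip-off) and
# tip-release (pull-off) detection, and detachment-curve mapping.
#
# The branch is parameterised by theta_obj, which varies monotonically
# along it, with the base angle freed as a shooting unknown. The push angle
# theta_p = theta0_touch - theta0 (positive into the pole for CB contacts)
# folds back at the saddle-node, so the fold is located as the extremum of
# theta_p along the branch.

#' Continue the contact solution branch from initial touch
#'
#' Starting from the barely-touching state (zero force, tangency), steps
#' the contact angle away from its initial-touch value in the direction
#' that pushes the whisker into the pole, re-solving the shooting problem
#' at each step. The continuation runs through the saddle-node fold onto
#' the unstable sub-branch (when `post_fold = TRUE`) and stops at pull-off
#' when the contact arclength reaches the whisker length.
#'
#' @inheritParams initial_touch
#' @param settings a [solver_settings()].
#' @param post_fold continue past a detected fold onto the unstable
#'   sub-branch.
#' @param post_fold_frac keep continuing past the fold until the push angle
#'   has dropped to this fraction of its critical value.
#' @param max_steps continuation step cap.
#' @return An object of class `whisker_branch`: `points` (data frame with
#'   `theta_obj_deg`, `theta0_deg`, `theta_p_deg`, `F`, `s_obj`, `d`,
#'   `energy`, `stable`), `direction` (`"CB"`/`"CF"`), `fold_index` (last
#'   stable row, `NA` without a fold), `event` (a `detachment_event` or
#'   `NULL`), and the inputs.
#' @export
continue_branch <- function(geom, pose, pole, settings = solver_settings(),
                            post_fold = TRUE, post_fold_frac = 0.25,
                            max_steps = 5000) {
  it <- initial_touch(geom, pose, pole)
  side <- if (it$side == "CB") 1 else -1
  pose_t <- pose
  pose_t$theta0 <- it$theta0_touch

  sol_at <- function(theta_obj, seed, J = NULL) {
    g <- list(F = seed$F, s_obj = seed$s_obj, theta0 = seed$theta0,
              theta_obj = theta_obj)
    ws_solve(geom, pose_t, pole, "theta_obj", g, settings, J = J, side = side)
  }
  theta_p_of <- function(sol) rad2deg(it$theta0_touch - sol$theta0)
  d_of <- function(sol) {
    xy <- ws_contact_xy(pole, sol$theta_obj, side)
    sqrt((xy[["x"]] - pose$x0)^2 + (xy[["y"]] - pose$y0)^2)
  }
  energy_of <- function(sol) {
    cheap <- settings; cheap$n_output <- 61
    ws_solution(geom, pose_t, pole, sol$theta0, sol$F, sol$theta_obj,
                sol$s_obj, cheap, side = side)$energy
  }

  seed0 <- list(F = 0, s_obj = it$s_obj, theta0 = it$theta0_touch)
  step0 <- deg2rad(settings$step_deg)

  # push direction: the contact-angle step whose solution carries a
  # positive (pushing) contact force
  dir <- NA_integer_
  for (sg in c(1L, -1L)) {
    tr <- sol_at(it$theta_obj + sg * step0, seed0)
    if (tr$converged && tr$F > 0) { dir <- sg; first <- tr; break }
  }
  if (is.na(dir))
    ws_stop("shooting failed: no pushing branch from initial touch",
            "vibrissa_solver_failure")

  # theta_p sign on this branch (positive CB, negative CF)
  tp_sign <- if (it$side == "CB") 1 else -1

  rec <- function(sol) {
    data.frame(theta_obj_deg = rad2deg(sol$theta_obj),
               theta0_deg = rad2deg(sol$theta0),
               theta_p_deg = theta_p_of(sol),
               F = sol$F, s_obj = sol$s_obj, d = d_of(sol),
               energy = energy_of(sol))
  }

  pts <- rbind(rec(list(F = 0, s_obj = it$s_obj, theta0 = it$theta0_touch,
                        theta_obj = it$theta_obj)),
               rec(first))
  seed <- first; J <- first$J
  step <- step0
  theta_obj <- it$theta_obj + dir * step0
  fold <- NULL; event <- NULL
  n_post <- 0

  for (k in seq_len(max_steps)) {
    sol <- sol_at(theta_obj + dir * step, seed, J = J)
    if (!sol$converged) {
      step <- step / 2
      J <- NULL
      if (step < deg2rad(settings$step_min_deg)) break
      next
    }
    theta_obj <- theta_obj + dir * step
    J <- sol$J; seed <- sol
    pts <- rbind(pts, rec(sol))
    n <- nrow(pts)
    v <- pts$theta_p_deg * tp_sign

    # pull-off: the contact reached the whisker tip
    if (is.null(fold) && sol$s_obj >= geom$L_w) {
      root <- ws_refine_pulloff(geom, pose_t, pole, pts, sol_at, side)
      event <- detachment_event("pull_off", root$theta_p * tp_sign, it$d,
                                geom$L_w, root$theta0)
      pts <- pts[pts$s_obj <= geom$L_w * (1 + 1e-9), , drop = FALSE]
      pts <- rbind(pts, root$row)
      break
    }

    # fold: the push angle passed through an extremum
    if (is.null(fold) && n >= 4 && v[n] < v[n - 1] && v[n - 1] >= v[n - 2]) {
      fr <- ws_refine_fold(pts, n, dir, sol_at, theta_p_of, tp_sign, settings)
      fold <- fr
      event <- detachment_event("slip_off", fr$theta_p_crit * tp_sign, it$d,
                                fr$s_obj, fr$theta0)
      if (!post_fold) break
    }
    if (!is.null(fold)) {
      n_post <- n_post + 1
      if (v[n] <= post_fold_frac * fold$theta_p_crit || v[n] <= 0) break
      if (geom$shape_kind == "conical" && sol$s_obj >= 0.995 * geom$L_w) break
      if (sol$s_obj > 1.5 * geom$L_w) break
    }
    if (abs(pts$theta_p_deg[n]) > settings$theta_p_max_deg) break

    # adaptive step: grow on easy convergence, already halved on failure
    if (sol$iters <= 3 && step < deg2rad(settings$step_max_deg))
      step <- min(step * 1.4, deg2rad(settings$step_max_deg))
  }

  fold_index <- if (is.null(fold)) NA_integer_ else fold$index_hint
  pts$stable <- if (is.na(fold_index)) rep(TRUE, nrow(pts)) else
    seq_len(nrow(pts)) <= fold_index
  structure(list(points = pts, direction = it$side, side_sign = side,
                 fold_index = fold_index,
                 fold = fold, event = event, touch = it,
                 geom = geom, pose = pose_t, pole = pole,
                 settings = settings),
            class = "whisker_branch")
}

# refine the pull-off point: root of s_obj - L_w in theta_obj on the last
# continuation interval
ws_refine_pulloff <- function(geom, pose_t, pole, pts, sol_at, side = 1) {
  n <- nrow(pts)
  lo <- deg2rad(pts$theta_obj_deg[n - 1]); hi <- deg2rad(pts$theta_obj_deg[n])
  seed_lo <- list(F = pts$F[n - 1], s_obj = pts$s_obj[n - 1],
                  theta0 = deg2rad(pts$theta0_deg[n - 1]))
  f <- function(to) {
    s <- sol_at(to, seed_lo)
    if (!s$converged) return(NA_real_)
    s$s_obj - geom$L_w
  }
  root <- tryCatch(stats::uniroot(f, c(lo, hi), tol = deg2rad(1e-4))$root,
                   error = function(e) hi)
  s <- sol_at(root, seed_lo)
  tp0 <- rad2deg(pose_t$theta0 - s$theta0)
  xy <- ws_contact_xy(pole, s$theta_obj, side)
  list(theta_p = abs(tp0), theta0 = s$theta0,
       row = data.frame(theta_obj_deg = rad2deg(root),
                        theta0_deg = rad2deg(s$theta0),
                        theta_p_deg = tp0, F = s$F, s_obj = s$s_obj,
                        d = sqrt((xy[["x"]] - pose_t$x0)^2 +
                                 (xy[["y"]] - pose_t$y0)^2),
                        energy = NA_real_))
}

# refine the saddle-node fold: maximise theta_p over theta_obj near the
# detected grid extremum
ws_refine_fold <- function(pts, n, dir, sol_at, theta_p_of, tp_sign, settings) {
  lo <- deg2rad(min(pts$theta_obj_deg[(n - 2):n]))
  hi <- deg2rad(max(pts$theta_obj_deg[(n - 2):n]))
  seed <- list(F = pts$F[n - 1], s_obj = pts$s_obj[n - 1],
               theta0 = deg2rad(pts$theta0_deg[n - 1]))
  last <- list(s_obj = pts$s_obj[n - 1], theta0 = deg2rad(pts$theta0_deg[n - 1]))
  fn <- function(to) {
    s <- sol_at(to, seed)
    if (!s$converged) return(-Inf)
    last$s_obj <<- s$s_obj; last$theta0 <<- s$theta0
    theta_p_of(s) * tp_sign
  }
  op <- stats::optimize(fn, c(lo, hi), maximum = TRUE,
                        tol = deg2rad(settings$fold_tol_deg) / 4)
  list(theta_p_crit = op$objective, theta_obj_crit = op$maximum,
       s_obj = last$s_obj, theta0 = last$theta0, index_hint = n - 1)
}

detachment_event <- function(kind, theta_p_crit_deg, d, s_obj, theta0) {
  structure(list(kind = kind, theta_p_crit_deg = theta_p_crit_deg,
                 d = d, s_obj_at_detach = s_obj,
                 theta0_crit = theta0),
            class = "detachment_event")
}

#' @export
print.detachment_event <- function(x, ...) {
  cat(sprintf("Detachment: %s at theta_p = %.3f deg (d = %.4g mm, s_obj = %.4g mm)\n",
              x$kind, x$theta_p_crit_deg, x$d * 1e3, x$s_obj_at_detach * 1e3))
  invisible(x)
}

#' @export
print.whisker_branch <- function(x, ...) {
  cat(sprintf("Contact branch (%s): %d points, theta_p in [%.3g, %.3g] deg\n",
              x$direction, nrow(x$points), min(x$points$theta_p_deg),
              max(x$points$theta_p_deg)))
  if (!is.null(x$event)) print(x$event) else cat("  no detachment located\n")
  invisible(x)
}

#' @export
plot.whisker_branch <- function(x, what = c("theta_obj", "F", "s_obj"), ...) {
  what <- match.arg(what)
  p <- x$points
  yv <- switch(what, theta_obj = p$theta_obj_deg, F = p$F * 1e6,
               s_obj = p$s_obj * 1e3)
  yl <- switch(what, theta_obj = "theta_obj (deg)", F = "F (uN)",
               s_obj = "s_obj (mm)")
  stable <- if (is.na(x$fold_index)) rep(TRUE, nrow(p)) else
    seq_len(nrow(p)) <= x$fold_index
  plot(p$theta_p_deg[stable], yv[stable], type = "l",
       xlim = range(p$theta_p_deg), ylim = range(yv),
       xlab = "push angle theta_p (deg)", ylab = yl, ...)
  if (any(!stable)) lines(p$theta_p_deg[!stable], yv[!stable], lty = 2)
  if (!is.null(x$event))
    points(x$event$theta_p_crit_deg,
           yv[which.max(p$theta_p_deg * sign(x$event$theta_p_crit_deg))],
           pch = 16)
  invisible(x)
}

#' Locate the detachment event for one whisker-pole configuration
#'
#' Continues the stable branch from initial touch and returns the first
#' detachment: a slip-off (saddle-node fold, contact still on the shaft) or
#' a pull-off (contact reaches the whisker tip).
#'
#' @inheritParams continue_branch
#' @return A `detachment_event`: `kind` (`"slip_off"`/`"pull_off"`),
#'   `theta_p_crit_deg` (signed: positive CB, negative CF), `d` (the
#'   base-contact distance at initial touch, m), `s_obj_at_detach` (m) and
#'   `theta0_crit` (radians).
#' @export
find_detachment <- function(geom, pose, pole, settings = solver_settings()) {
  br <- continue_branch(geom, pose, pole, settings, post_fold = FALSE)
  if (is.null(br$event))
    ws_stop("no detachment in range: continuation hit the push-angle cap",
            "vibrissa_no_solution")
  br$event
}

#' Place a pole tangent to the undeflected whisker at a given distance
#'
#' Positions a pole of radius `r_pole` tangent to the undeflected whisker
#' such that the Euclidean base-to-contact distance equals `d`, on the
#' concave-backward (CB, convex) or concave-forward (CF, concave) side.
#'
#' @inheritParams undeflected_shape
#' @param d base-to-contact distance, metres.
#' @param r_pole pole radius, metres.
#' @param side `"CB"` or `"CF"`.
#' @return A [pole()] object.
#' @export
place_pole_at_distance <- function(geom, pose, d, r_pole,
                                   side = c("CB", "CF")) {
  side <- match.arg(side)
  chord <- function(s) {
    p <- undeflected_point(s, geom, pose)
    sqrt((p$x - pose$x0)^2 + (p$y - pose$y0)^2) - d
  }
  if (chord(geom$L_w) < 0)
    stop("unreachable: d exceeds the whisker's base-to-tip distance")
  s_t <- stats::uniroot(chord, c(1e-9 * geom$L_w, geom$L_w), tol = 1e-13)$root
  p <- undeflected_point(s_t, geom, pose)
  sgn <- if (side == "CB") -1 else 1      # CB: convex side (right of tangent)
  nx <- -sin(p$theta) * sgn; ny <- cos(p$theta) * sgn
  pole(r_pole * 1e3, (p$x + r_pole * nx) * 1e3, (p$y + r_pole * ny) * 1e3)
}

#' Map the detachment curve in the push-angle/object-distance plane
#'
#' For each requested object distance `d`, places a pole tangent to the
#' undeflected whisker on the requested side(s) and locates the detachment
#' event. The resulting set of critical push angles bounds the region of
#' the plane where a stable contacting solution exists.
#'
#' @inheritParams continue_branch
#' @param r_pole pole radius, metres.
#' @param d_values object distances, metres.
#' @param directions subset of `c("CB", "CF")`.
#' @param pose the [base_pose()] used to lay out the undeflected whisker.
#' @return An object of class `detachment_curve`: a data frame with columns
#'   `direction`, `d`, `theta_p_crit_deg`, `kind`, `s_obj_at_detach`, plus
#'   a parameter snapshot in `attr(, "params")`.
#' @export
detachment_curve <- function(geom, r_pole, d_values,
                             directions = c("CB", "CF"),
                             pose = base_pose(),
                             settings = solver_settings()) {
  rows <- list()
  for (dir in directions) {
    for (d in d_values) {
      row <- tryCatch({
        pl <- place_pole_at_distance(geom, pose, d, r_pole, dir)
        ev <- find_detachment(geom, pose, pl, settings)
        data.frame(direction = dir, d = d,
                   theta_p_crit_deg = ev$theta_p_crit_deg,
                   kind = ev$kind, s_obj_at_detach = ev$s_obj_at_detach)
      }, error = function(e) {
        data.frame(direction = dir, d = d, theta_p_crit_deg = NA_real_,
                   kind = if (grepl("unreachable", conditionMessage(e)))
                     "unreachable" else "failed",
                   s_obj_at_detach = NA_real_)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(geom = unclass(geom), r_pole = r_pole,
                              pose = unclass(pose))
  class(out) <- c("detachment_curve", "data.frame")
  out
}

#' @export
print.detachment_curve <- function(x, ...) {
  cat("Detachment curve:\n")
  print.data.frame(transform(as.data.frame(x), d_mm = d * 1e3,
                             s_obj_mm = s_obj_at_detach * 1e3)[
                     , c("direction", "d_mm", "theta_p_crit_deg", "kind",
                         "s_obj_mm")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.detachment_curve <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$theta_p_crit_deg), ]
  plot(df$d * 1e3, df$theta_p_crit_deg, type = "n",
       xlab = "object distance d (mm)", ylab = "critical theta_p (deg)", ...)
  for (dir in unique(df$direction)) {
    for (knd in unique(df$kind)) {
      sel <- df$direction == dir & df$kind == knd
      if (!any(sel)) next
      lines(df$d[sel] * 1e3, df$theta_p_crit_deg[sel],
            col = if (knd == "pull_off") "blue" else "black",
            lty = if (dir == "CF") 2 else 1)
      points(df$d[sel] * 1e3, df$theta_p_crit_deg[sel], pch = 20,
             col = if (knd == "pull_off") "blue" else "black")
    }
  }
  invisible(x)
}

#' Write a detachment curve to CSV with a JSON parameter manifest
#'
#' @param x a `detachment_curve`.
#' @param csv_path output CSV path.
#' @param json_path output JSON path for the parameter snapshot; default
#'   replaces the CSV extension.
#' @return Invisibly, the paths written.
#' @export
write_detachment_curve <- function(x, csv_path,
                                   json_path = sub("\\.csv$", ".json",
                                                   csv_path)) {
  df <- as.data.frame(x)
  names(df) <- c("direction", "d_m", "theta_p_crit_deg", "kind",
                 "s_obj_at_detach_m")
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(attr(x, "params"), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' @export
summary.whisker_branch <- function(object, ...) {
  p <- object$points
  cat(sprintf("Contact branch (%s): %d points\n", object$direction, nrow(p)))
  cat(sprintf("  theta_p: [%.3f, %.3f] deg; F up to %.4g uN; s_obj up to %.4g mm\n",
              min(p$theta_p_deg), max(p$theta_p_deg), max(p$F) * 1e6,
              max(p$s_obj) * 1e3))
  if (!is.na(object$fold_index))
    cat(sprintf("  saddle-node fold after point %d\n", object$fold_index))
  if (!is.null(object$event)) print(object$event)
  invisible(object)
}
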