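# Quasi-static sweep simulation: a whisker mounted at a fixed base point is
# slowly rotated against a pole (the galvo protocol). Every frame is the
# static solution for the instantaneous base angle; events are interpolated
# between frames by bisection on the base angle, so their timing does not
# depend on the frame rate.

#' Rotation sweep protocol
#'
#' Describes the periodic drive applied to the whisker base. Galvo scanners
#' are conventionally driven sinusoidally at low frequency; a triangle wave
#' is available as an alternative.
#'
#' @param f_hz rotation frequency, Hz.
#' @param amplitude_pp_deg peak-to-peak angular amplitude, degrees
#'   (`<= 360`).
#' @param duration_s sweep duration, seconds; defaults to one period.
#' @param frame_rate samples per second.
#' @param phase0_deg initial phase, degrees.
#' @param theta_center_deg centre angle of the oscillation, degrees.
#' @param waveform `"sine"` or `"triangle"`.
#' @return A list of class `sweep_protocol`.
#' @export
sweep_protocol <- function(f_hz = 0.2, amplitude_pp_deg = 30,
                           duration_s = 1 / f_hz, frame_rate = 32,
                           phase0_deg = 0, theta_center_deg = 0,
                           waveform = c("sine", "triangle")) {
  stopifnot(f_hz > 0, amplitude_pp_deg >= 0, amplitude_pp_deg <= 360,
            duration_s > 0, frame_rate > 0)
  structure(list(f_hz = f_hz, amplitude_pp_deg = amplitude_pp_deg,
                 duration_s = duration_s, frame_rate = frame_rate,
                 phase0_deg = phase0_deg,
                 theta_center_deg = theta_center_deg,
                 waveform = match.arg(waveform)),
            class = "sweep_protocol")
}

#' Base-pose trajectory for a sweep protocol
#'
#' Samples the drive waveform at the protocol's frame rate. The base
#' position is fixed; only the base angle varies:
#' `theta0(t) = theta_center + (A_pp / 2) sin(2 pi f t + phase0)`.
#'
#' @param protocol a [sweep_protocol()].
#' @param pose the [base_pose()] providing the fixed base position (its
#'   `theta0_deg` is added to the protocol's centre angle).
#' @return A data frame of class `galvo_trajectory` with columns `t` (s)
#'   and `theta0_deg`; the base position is kept in attributes.
#' @export
galvo_trajectory <- function(protocol, pose = base_pose()) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  # half-open sampling: one period at 32 fps gives exactly 160 frames
  t <- seq(0, protocol$duration_s - 1 / protocol$frame_rate,
           by = 1 / protocol$frame_rate)
  ph <- 2 * pi * protocol$f_hz * t + deg2rad(protocol$phase0_deg)
  osc <- switch(protocol$waveform,
                sine = sin(ph),
                triangle = 2 / pi * asin(sin(ph)))
  th <- protocol$theta_center_deg + rad2deg(pose$theta0) +
    protocol$amplitude_pp_deg / 2 * osc
  out <- data.frame(t = t, theta0_deg = th)
  attr(out, "x0") <- pose$x0
  attr(out, "y0") <- pose$y0
  attr(out, "protocol") <- protocol
  class(out) <- c("galvo_trajectory", "data.frame")
  out
}

#' Simulate a quasi-static sweep against a pole
#'
#' Steps through a base-pose trajectory. At each frame the whisker is
#' either free (its undeflected shape does not reach the pole) or in
#' contact, in which case the static contact solution is computed by
#' shooting, seeded from the previous frame. Contact episodes are opened by
#' a `touch_onset` event (tangency, push angle zero) and closed by one of:
#' `slip_off` (the stable solution ceases to exist between two frames;
#' located by bisection on the base angle), `pull_off` (the contact
#' arclength reaches the whisker length) or `release` (the push angle
#' returns through zero and the whisker leaves the pole). After a slip or
#' pull the whisker is taken to spring instantaneously to its free shape;
#' frames in which the free shape still overlaps the pole are flagged in
#' the `passing` column and no re-contact is attempted until the overlap
#' clears.
#'
#' @inheritParams continue_branch
#' @param trajectory a [galvo_trajectory()] (or data frame with `t`,
#'   `theta0_deg` plus `x0`/`y0` attributes).
#' @return An object of class `whisker_sweep`: `frames` (data frame with
#'   `t`, `theta0_deg`, `in_contact`, `passing`, `theta_p_deg`, `F`,
#'   `s_obj`, `d`), `events` (data frame with `t`, `type`, `theta_p_deg`,
#'   `d`, `s_obj`), and the inputs.
#' @export
simulate_sweep <- function(geom, trajectory, pole,
                           settings = solver_settings()) {
  x0 <- attr(trajectory, "x0") %||% 0
  y0 <- attr(trajectory, "y0") %||% 0
  pose_at <- function(theta0_deg) {
    p <- base_pose(); p$x0 <- x0; p$y0 <- y0; p$theta0 <- deg2rad(theta0_deg)
    p
  }
  gap_at <- function(theta0_deg)
    pole_gap(geom, pose_at(theta0_deg), pole)$gap

  nf <- nrow(trajectory)
  frames <- data.frame(t = trajectory$t, theta0_deg = trajectory$theta0_deg,
                       in_contact = FALSE, passing = FALSE,
                       theta_p_deg = NA_real_, F = NA_real_,
                       s_obj = NA_real_, d = NA_real_,
                       theta_obj_deg = NA_real_, side_sign = NA_real_)
  events <- list()
  add_event <- function(t, type, theta_p, d, s_obj) {
    events[[length(events) + 1]] <<-
      data.frame(t = t, type = type, theta_p_deg = theta_p, d = d,
                 s_obj = s_obj)
  }
  # event time from the base angle by linear interpolation on the frame pair
  t_of_theta <- function(i, theta0_deg) {
    th <- trajectory$theta0_deg
    if (abs(th[i] - th[i - 1]) < 1e-12) return(trajectory$t[i])
    trajectory$t[i - 1] + (theta0_deg - th[i - 1]) / (th[i] - th[i - 1]) *
      (trajectory$t[i] - trajectory$t[i - 1])
  }

  state <- "free"
  seed <- NULL; J <- NULL
  theta0_touch <- NA_real_
  side <- 1

  solve_frame <- function(theta0_deg, seed, J = NULL) {
    ws_solve(geom, pose_at(theta0_deg), pole, "pose", seed, settings, J = J,
             side = side)
  }

  for (i in seq_len(nf)) {
    th_i <- trajectory$theta0_deg[i]
    g_i <- gap_at(th_i)

    if (state == "free") {
      if (g_i < 0 && i > 1) {
        # new contact: bisect to the tangency angle and open an episode
        th_prev <- trajectory$theta0_deg[i - 1]
        th_touch <- tryCatch(
          stats::uniroot(function(th) gap_at(th), sort(c(th_prev, th_i)),
                         tol = 1e-10)$root,
          error = function(e) th_prev)
        it <- initial_touch(geom, pose_at(th_touch), pole)
        theta0_touch <- rad2deg(it$theta0_touch)
        side <- if (it$side == "CB") 1 else -1
        add_event(t_of_theta(i, th_touch), "touch_onset", 0, it$d, it$s_obj)
        seed <- list(F = 0, theta_obj = it$theta_obj, s_obj = it$s_obj)
        J <- NULL
        state <- "contact"
      } else if (g_i < 0 && i == 1) {
        # trajectory starts in contact: anchor the push angle at tangency
        it <- initial_touch(geom, pose_at(th_i), pole)
        theta0_touch <- rad2deg(it$theta0_touch)
        side <- if (it$side == "CB") 1 else -1
        seed <- list(F = 0, theta_obj = it$theta_obj, s_obj = it$s_obj)
        J <- NULL
        state <- "contact"
      }
    }

    if (state == "contact") {
      sol <- solve_frame(th_i, seed, J)
      if (sol$converged && sol$F < 0 && i == 1) {
        # starting pose touches but the episode opens unloaded
        state <- "free"; seed <- NULL; J <- NULL
      } else if (sol$converged && sol$F < 0) {
        # the drive rotated back through the touch angle: the contact
        # force crosses zero and the whisker separates (push angle ~ 0)
        th_prev <- trajectory$theta0_deg[i - 1]
        f <- function(th) {
          s <- solve_frame(th, seed)
          if (!s$converged) return(NA_real_)
          s$F
        }
        th_rel <- tryCatch(
          stats::uniroot(f, sort(c(th_prev, th_i)), tol = 1e-8)$root,
          error = function(e) th_i)
        sr <- solve_frame(th_rel, seed)
        add_event(t_of_theta(i, th_rel), "release", theta0_touch - th_rel,
                  if (sr$converged) {
                    xy <- ws_contact_xy(pole, sr$theta_obj, side)
                    sqrt((xy[["x"]] - x0)^2 + (xy[["y"]] - y0)^2)
                  } else NA_real_,
                  if (sr$converged) sr$s_obj else NA_real_)
        state <- "free"
        seed <- NULL; J <- NULL
      } else {
        if (sol$converged && sol$s_obj < geom$L_w) {
          frames$in_contact[i] <- TRUE
          frames$theta_p_deg[i] <- theta0_touch - th_i
          frames$F[i] <- sol$F
          frames$s_obj[i] <- sol$s_obj
          frames$theta_obj_deg[i] <- rad2deg(sol$theta_obj)
          frames$side_sign[i] <- side
          xy <- ws_contact_xy(pole, sol$theta_obj, side)
          frames$d[i] <- sqrt((xy[["x"]] - x0)^2 + (xy[["y"]] - y0)^2)
          seed <- list(F = sol$F, theta_obj = sol$theta_obj,
                       s_obj = sol$s_obj)
          J <- sol$J
        } else if (sol$converged) {
          # contact arclength reached the tip between frames: pull-off
          th_prev <- trajectory$theta0_deg[i - 1]
          f <- function(th) {
            s <- solve_frame(th, seed)
            if (!s$converged) return(NA_real_)
            s$s_obj - geom$L_w
          }
          th_pull <- tryCatch(
            stats::uniroot(f, sort(c(th_prev, th_i)), tol = 1e-8)$root,
            error = function(e) th_prev)
          sp <- solve_frame(th_pull, seed)
          add_event(t_of_theta(i, th_pull), "pull_off",
                    theta0_touch - th_pull,
                    if (sp$converged) {
                      xy <- ws_contact_xy(pole, sp$theta_obj, side)
                      sqrt((xy[["x"]] - x0)^2 + (xy[["y"]] - y0)^2)
                    } else NA_real_,
                    geom$L_w)
          state <- "passing"
          seed <- NULL; J <- NULL
        } else {
          # no static solution: the fold was crossed between frames.
          # bisect on the base angle for the last solvable pose
          th_lo <- trajectory$theta0_deg[i - 1]   # solvable
          th_hi <- th_i                           # not solvable
          seed_lo <- seed
          for (b in 1:24) {
            th_mid <- (th_lo + th_hi) / 2
            sm <- solve_frame(th_mid, seed_lo)
            if (sm$converged && sm$s_obj < geom$L_w) {
              th_lo <- th_mid
              seed_lo <- list(F = sm$F, theta_obj = sm$theta_obj,
                              s_obj = sm$s_obj)
            } else th_hi <- th_mid
            if (abs(th_hi - th_lo) < 1e-4) break
          }
          sm <- solve_frame(th_lo, seed_lo)
          d_slip <- if (sm$converged) {
            xy <- ws_contact_xy(pole, sm$theta_obj, side)
            sqrt((xy[["x"]] - x0)^2 + (xy[["y"]] - y0)^2)
          } else NA_real_
          add_event(t_of_theta(i, th_lo), "slip_off", theta0_touch - th_lo,
                    d_slip, if (sm$converged) sm$s_obj else NA_real_)
          state <- "passing"
          seed <- NULL; J <- NULL
        }
      }
    }

    if (state == "passing") {
      frames$passing[i] <- g_i < 0
      if (g_i >= 0) state <- "free"
    }
    if (!frames$in_contact[i]) frames$F[i] <- 0
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(t = numeric(0), type = character(0),
               theta_p_deg = numeric(0), d = numeric(0), s_obj = numeric(0))
  ev <- ev[order(ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(frames = frames, events = ev, geom = geom, pole = pole,
                 trajectory = trajectory, settings = settings),
            class = "whisker_sweep")
}

#' @export
print.whisker_sweep <- function(x, ...) {
  cat(sprintf("Quasi-static sweep: %d frames (%.3g s), %d in contact\n",
              nrow(x$frames), max(x$frames$t), sum(x$frames$in_contact)))
  if (nrow(x$events)) {
    cat("Events:\n")
    print.data.frame(x$events, digits = 4, row.names = FALSE)
  } else cat("No events\n")
  invisible(x)
}

#' @export
plot.whisker_sweep <- function(x, ...) {
  f <- x$frames
  plot(f$t, f$theta_p_deg, type = "l", xlab = "time (s)",
       ylab = "push angle theta_p (deg)", ...)
  abline(h = 0, col = "grey70")
  if (nrow(x$events)) {
    sl <- x$events[x$events$type %in% c("slip_off", "pull_off"), ]
    if (nrow(sl)) points(sl$t, sl$theta_p_deg, pch = 16, col = "red")
  }
  invisible(x)
}

#' Tabulate sweep events
#'
#' @param result a `whisker_sweep`.
#' @return A data frame, one row per event, sorted by time, with columns
#'   `t`, `type`, `theta_p_deg`, `d`, `s_obj`.
#' @export
event_table <- function(result) {
  stopifnot(inherits(result, "whisker_sweep"))
  result$events
}

#' @export
summary.whisker_sweep <- function(object, ...) {
  f <- object$frames
  cat(sprintf("Quasi-static sweep: %d frames over %.3g s\n", nrow(f), max(f$t)))
  cat(sprintf("  in contact: %d frames; peak |theta_p| = %.3f deg; peak F = %.4g uN\n",
              sum(f$in_contact),
              if (any(f$in_contact)) max(abs(f$theta_p_deg), na.rm = TRUE) else 0,
              if (any(f$in_contact)) max(f$F, na.rm = TRUE) * 1e6 else 0))
  tab <- table(object$events$type)
  if (length(tab)) {
    cat("  events: ")
    cat(paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "))
    cat("\n")
  }
  invisible(object)
}
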