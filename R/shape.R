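# Analysis of tracked whisker medial-axis point sequences: base-angle and
# push-angle estimation, out-of-plane projection correction and effective-
# length calibration, plus a seeded synthetic fixture generator emulating
# high-speed videography so the whole chain is testable without video.

#' A tracked whisker frame
#'
#' One video frame's whisker medial axis as an ordered point list, base
#' first. Points are re-ordered by distance from the declared base point
#' before analysis, since tracker output order is not guaranteed.
#'
#' @param t frame time, seconds.
#' @param points two-column matrix (x, y) in metres, at least 10 points.
#' @param pixel_size image scale, metres per pixel.
#' @param base_xy optional explicit base position (m); defaults to the
#'   first supplied point.
#' @return An object of class `tracked_frame`.
#' @export
tracked_frame <- function(t, points, pixel_size, base_xy = points[1, ]) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an N x 2 matrix")
  if (nrow(points) < 10)
    stop("insufficient points: at least 10 required for the base fit")
  o <- order(sqrt((points[, 1] - base_xy[1])^2 +
                  (points[, 2] - base_xy[2])^2))
  points <- points[o, , drop = FALSE]
  step <- sqrt(rowSums((points[-1, , drop = FALSE] -
                        points[-nrow(points), , drop = FALSE])^2))
  if (any(step == 0)) stop("consecutive points must not coincide")
  structure(list(t = t, points = points, pixel_size = pixel_size),
            class = "tracked_frame")
}

#' @export
print.tracked_frame <- function(x, ...) {
  cat(sprintf("Tracked frame t = %.4g s: %d points, pixel %.3g mm\n",
              x$t, nrow(x$points), x$pixel_size * 1e3))
  invisible(x)
}

#' Estimate the base angle from a tracked frame
#'
#' Tracking is noisy right at the base (fur, follicle), so the base angle
#' is estimated from a short segment just beyond it: an orthogonal
#' (total-least-squares) line fit of the fifth through tenth points closest
#' to the base, by default.
#'
#' @param frame a [tracked_frame()].
#' @param fit_points indices (1-based, after ordering by distance from the
#'   base) of the points entering the fit.
#' @return Base angle in degrees, oriented from base towards tip.
#' @export
estimate_base_angle <- function(frame, fit_points = 5:10) {
  stopifnot(inherits(frame, "tracked_frame"))
  if (nrow(frame$points) < max(fit_points))
    stop("insufficient points for the requested base fit")
  pts <- frame$points[fit_points, , drop = FALSE]
  pc <- stats::prcomp(pts)
  v <- pc$rotation[, 1]
  # orient along increasing distance from the base
  ref <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v * ref) < 0) v <- -v
  rad2deg(atan2(v[2], v[1]))
}

#' Extract the push angle from a tracked frame
#'
#' Applies the virtual-contact construction to tracked data: the base pose
#' is taken from the declared base point and [estimate_base_angle()], the
#' contact point is the tracked point closest to the pole circle (snapped
#' radially onto it), and [push_angle()] does the geometry. With the
#' default `"curvature"` convention the sign is positive for
#' concave-backward contacts; the `"protraction"` convention, used for
#' behaving animals where torsion decouples the sign from intrinsic
#' curvature, assigns the sign from the supplied movement direction
#' instead.
#'
#' @param frame a [tracked_frame()].
#' @param geom a [whisker_geometry()] describing the undeflected whisker.
#' @param pole a [pole()].
#' @param gate maximum distance of a tracked point from the pole surface to
#'   accept a contact, metres; defaults to 10 pixels.
#' @param sign_convention `"curvature"` or `"protraction"`.
#' @param moving movement direction, used by the `"protraction"` convention
#'   only.
#' @param fit_points points entering the base-angle fit (see
#'   [estimate_base_angle()]). The fitted direction estimates the tangent
#'   near the middle of this span, not at the base itself; the local
#'   curvature measured from the track (intrinsic plus load-induced) is
#'   used to transfer it back to the base, which matters for strongly
#'   curved whiskers.
#' @param mirror set to `TRUE` for scenes in which the whisker curves
#'   clockwise (concave-down imaging); the frame and pole are reflected
#'   into the canonical orientation and the sign of the result flipped
#'   back.
#' @return Signed push angle in degrees.
#' @export
extract_push_angle <- function(frame, geom, pole,
                               gate = 10 * frame$pixel_size,
                               sign_convention = c("curvature", "protraction"),
                               moving = c("protraction", "retraction"),
                               fit_points = 5:10, mirror = FALSE) {
  sign_convention <- match.arg(sign_convention)
  moving <- match.arg(moving)
  if (mirror) {
    fr2 <- tracked_frame(frame$t, cbind(frame$points[, 1], -frame$points[, 2]),
                         frame$pixel_size)
    pole2 <- pole
    pole2$y_cen <- -pole$y_cen
    tp <- -extract_push_angle(fr2, geom, pole2, gate, "curvature",
                              fit_points = fit_points)
    if (sign_convention == "protraction")
      tp <- abs(tp) * if (moving == "protraction") 1 else -1
    return(tp)
  }
  pts <- frame$points
  dist_c <- sqrt((pts[, 1] - pole$x_cen)^2 + (pts[, 2] - pole$y_cen)^2)
  miss <- abs(dist_c - pole$r_pole)
  in_gate <- which(miss <= gate)
  if (length(in_gate) == 0)
    stop("no contact in frame: no tracked point near the pole")
  # the free segment beyond the contact can also pass close to the pole:
  # keep the first contiguous in-gate cluster and take its best point
  brk <- which(diff(in_gate) > 1)
  cluster <- if (length(brk)) in_gate[seq_len(brk[1])] else in_gate
  i <- cluster[which.min(miss[cluster])]
  # sub-point refinement: closest approach to the pole centre along the
  # interpolated polyline around the best point, then snap radially onto
  # the circle
  lo <- max(i - 1, 1); hi <- min(i + 1, nrow(pts))
  tt <- seq(0, 1, length.out = 51)
  best <- c(pts[i, 1], pts[i, 2]); best_d <- dist_c[i]
  for (j in lo:(hi - 1)) {
    px <- pts[j, 1] + tt * (pts[j + 1, 1] - pts[j, 1])
    py <- pts[j, 2] + tt * (pts[j + 1, 2] - pts[j, 2])
    dd <- sqrt((px - pole$x_cen)^2 + (py - pole$y_cen)^2)
    k <- which.min(dd)
    if (dd[k] < best_d) { best <- c(px[k], py[k]); best_d <- dd[k] }
  }
  u <- (best - c(pole$x_cen, pole$y_cen)) / best_d
  contact <- list(x_obj = pole$x_cen + pole$r_pole * u[1],
                  y_obj = pole$y_cen + pole$r_pole * u[2])
  pose <- base_pose()
  pose$x0 <- pts[1, 1]; pose$y0 <- pts[1, 2]
  # The line fit estimates the tangent at the middle of the fitted span,
  # not at the base. Transfer it back using the curvature measured from
  # the track itself (a quadratic fit over a wider window), which captures
  # both the intrinsic and the load-induced bending near the base.
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s_pts <- c(0, cumsum(seg))
  s_mid <- mean(s_pts[fit_points])
  th_line <- deg2rad(estimate_base_angle(frame, fit_points))
  win <- min(fit_points[1], 3):min(nrow(pts), max(fit_points) + 10)
  ctr <- colMeans(pts[win, , drop = FALSE])
  xr <- cos(th_line) * (pts[win, 1] - ctr[1]) +
    sin(th_line) * (pts[win, 2] - ctr[2])
  yr <- -sin(th_line) * (pts[win, 1] - ctr[1]) +
    cos(th_line) * (pts[win, 2] - ctr[2])
  cf <- stats::lm.fit(cbind(1, xr, xr^2), yr)$coefficients
  x_base <- cos(th_line) * (pts[1, 1] - ctr[1]) +
    sin(th_line) * (pts[1, 2] - ctr[2])
  slope_at <- function(x) cf[2] + 2 * cf[3] * x
  drift <- atan(slope_at(x_base + s_mid)) - atan(slope_at(x_base))
  pose$theta0 <- th_line - drift
  tp <- push_angle(pose, contact, geom)
  if (sign_convention == "protraction")
    tp <- abs(tp) * if (moving == "protraction") 1 else -1
  tp
}

#' Correct a projected arclength for constant out-of-plane elevation
#'
#' When the whisker droops out of the imaging plane at an approximately
#' constant elevation, arclengths measured on the projection underestimate
#' the true arclength by the cosine of the elevation.
#'
#' @param projected_s projected arclength(s), metres.
#' @param elevation_deg out-of-plane elevation, degrees (`|elevation| <
#'   90`).
#' @return A list with `s` (corrected arclength, same shape as
#'   `projected_s`) and `factor` (the multiplicative correction, `>= 1`).
#' @export
projected_arclength_correction <- function(projected_s, elevation_deg) {
  if (any(abs(elevation_deg) >= 90))
    stop("elevation must satisfy |elevation| < 90 degrees")
  factor <- 1 / cos(deg2rad(elevation_deg))
  list(s = projected_s * factor, factor = factor)
}

#' Calibrate the effective whisker length from slip-off events
#'
#' The whisker base is hard to place on video (fur), so the effective
#' length is estimated mechanically: the truncated length `L_w` is adjusted
#' until the model's predicted slip-off angle at the largest object
#' distance showing a slip-off matches the observed one. Radii, modulus and
#' intrinsic curvature are taken from `geom`; only `L_w` varies.
#'
#' @param slip_events data frame with columns `d` (m) and `theta_p_deg`
#'   (signed critical push angles of observed slip-offs).
#' @param geom a [whisker_geometry()] supplying everything except the
#'   length.
#' @param r_pole pole radius, metres.
#' @param pose base pose used to lay out the undeflected whisker.
#' @param settings solver settings; a coarser continuation than the default
#'   is adequate here.
#' @param tol_deg convergence tolerance on the matched critical angle.
#' @return The calibrated length `L_w` in metres, with the matched event as
#'   attribute `"event"`.
#' @export
calibrate_effective_length <- function(slip_events, geom, r_pole,
                                       pose = base_pose(),
                                       settings = solver_settings(
                                         step_deg = 1, fold_tol_deg = 0.05),
                                       tol_deg = 0.1) {
  stopifnot(is.data.frame(slip_events), nrow(slip_events) >= 1,
            all(c("d", "theta_p_deg") %in% names(slip_events)))
  ev <- slip_events[which.max(slip_events$d), ]
  side <- if (ev$theta_p_deg >= 0) "CB" else "CF"
  target <- abs(ev$theta_p_deg)

  crit_at <- function(L_w) {
    g <- whisker_geometry(L_w * 1e3, geom$r_base * 1e6, geom$r_tip * 1e6,
                          geom$E / 1e9, geom$A / 1e3, geom$x_vertex * 1e3)
    pl <- place_pole_at_distance(g, pose, ev$d, r_pole, side)
    det <- find_detachment(g, pose, pl, settings)
    if (det$kind != "slip_off") return(NA_real_)
    abs(det$theta_p_crit_deg)
  }

  # shortest length still reaching the contact distance
  chord_arclen <- function(d) {
    f <- function(s) {
      p <- parab_point_s(s, geom$A, geom$x_vertex)
      sqrt(p$x^2 + p$y^2) - d
    }
    stats::uniroot(f, c(d / 2, 4 * d), tol = 1e-12)$root
  }
  lo <- 1.01 * chord_arclen(ev$d)
  hi <- max(2.2 * ev$d, 1.5 * lo)
  f <- function(L_w) {
    v <- crit_at(L_w)
    if (is.na(v)) return(-target)   # pull-off regime: length too short
    v - target
  }
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("calibration failed: no length in the physical bracket fits")
  root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = 1e-5 * ev$d)$root
  if (abs(f(root)) > tol_deg + 0.5)
    stop("calibration failed: matched angle off by more than tolerance")
  structure(root, event = ev)
}

#' Synthetic tracked-data fixture specification
#'
#' Describes a synthetic videography session: model-generated whisker
#' shapes sampled at a fixed number of points with isotropic Gaussian
#' "pixel" noise. Purely synthetic stand-in for tracked video.
#'
#' @param geom,pole whisker and pole.
#' @param trajectory a [galvo_trajectory()] (or data frame `t`,
#'   `theta0_deg`).
#' @param n_points points per frame (>= 10).
#' @param pixel_noise_sd isotropic noise s.d., metres.
#' @param pixel_size metres per pixel recorded in the frames.
#' @param seed integer RNG seed; fixtures are bit-reproducible.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(geom, pole, trajectory, n_points = 60,
                         pixel_noise_sd = 0, pixel_size = 0.031e-3,
                         seed = 1) {
  stopifnot(n_points >= 10, pixel_noise_sd >= 0)
  structure(list(geom = geom, pole = pole, trajectory = trajectory,
                 n_points = n_points, pixel_noise_sd = pixel_noise_sd,
                 pixel_size = pixel_size, seed = seed),
            class = "fixture_spec")
}

# whisker shape over the full length [0, L_w]: the contact solution on
# [0, s_obj] continued by the undeflected (intrinsic) shape beyond the
# contact point, sampled at n points equally spaced in arclength
ws_full_curve <- function(geom, pose, pole, theta0, F, theta_obj, s_obj,
                          settings, n = 120, side = 1) {
  s_all <- seq(0, geom$L_w, length.out = n)
  in_c <- s_all <= s_obj
  sets <- settings; sets$n_output <- max(sum(in_c), 2)
  sig <- c(s_all[in_c] / s_obj, 1)
  out <- ws_integrate(geom, pole, pose$x0, pose$y0, theta0, F, theta_obj,
                      s_obj, sets, sigma = unique(sig), side = side)
  xy <- cbind(out[seq_len(sum(in_c)), "x"], out[seq_len(sum(in_c)), "y"])
  if (any(!in_c)) {
    # distal free segment: intrinsic parabola rigidly attached at the
    # contact point with matching tangent
    end <- out[nrow(out), ]
    p_c <- parab_point_s(s_obj, geom$A, geom$x_vertex)
    phi <- end[["theta"]] - p_c$theta
    pd <- parab_point_s(s_all[!in_c], geom$A, geom$x_vertex)
    dx <- pd$x - p_c$x; dy <- pd$y - p_c$y
    xy <- rbind(xy, cbind(end[["x"]] + cos(phi) * dx - sin(phi) * dy,
                          end[["y"]] + sin(phi) * dx + cos(phi) * dy))
  }
  list(s = s_all, x = xy[, 1], y = xy[, 2])
}

#' Generate synthetic tracked frames
#'
#' Runs the quasi-static sweep for the fixture's trajectory and samples
#' each frame's whisker shape (contact solution where contacting, free
#' shape otherwise) at `n_points` equally spaced in arclength, adding
#' seeded isotropic Gaussian noise.
#'
#' @param spec a [fixture_spec()].
#' @param settings a [solver_settings()].
#' @return A list of [tracked_frame()] objects; the generating sweep is
#'   attached as attribute `"sweep"`.
#' @export
generate_fixture <- function(spec, settings = solver_settings()) {
  stopifnot(inherits(spec, "fixture_spec"))
  geom <- spec$geom
  sw <- simulate_sweep(geom, spec$trajectory, spec$pole, settings)
  x0 <- attr(spec$trajectory, "x0") %||% 0
  y0 <- attr(spec$trajectory, "y0") %||% 0
  set.seed(spec$seed)
  frames <- vector("list", nrow(sw$frames))
  for (i in seq_len(nrow(sw$frames))) {
    fr <- sw$frames[i, ]
    pose <- base_pose()
    pose$x0 <- x0; pose$y0 <- y0; pose$theta0 <- deg2rad(fr$theta0_deg)
    if (isTRUE(fr$in_contact)) {
      # re-solve from the recorded state to recover the curve
      seed <- list(F = fr$F, theta_obj = deg2rad(fr$theta_obj_deg),
                   s_obj = fr$s_obj)
      sol <- ws_solve(geom, pose, spec$pole, "pose", seed, settings,
                      side = fr$side_sign)
      cu <- ws_full_curve(geom, pose, spec$pole, pose$theta0, sol$F,
                          sol$theta_obj, sol$s_obj, settings,
                          n = spec$n_points, side = fr$side_sign)
      pts <- cbind(cu$x, cu$y)
    } else {
      s <- seq(0, geom$L_w, length.out = spec$n_points)
      p <- undeflected_point(s, geom, pose)
      pts <- cbind(p$x, p$y)
    }
    if (spec$pixel_noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$pixel_noise_sd),
                          ncol = 2)
    frames[[i]] <- tracked_frame(fr$t, pts, spec$pixel_size,
                                 base_xy = c(x0, y0))
  }
  attr(frames, "sweep") <- sw
  frames
}

#' Write tracked frames as per-frame CSV files with a JSON manifest
#'
#' Each frame becomes `frame_<k>.csv` with columns `i`, `x`, `y` (metres);
#' `manifest.json` records the pixel size, frame times and base side.
#'
#' @param frames list of [tracked_frame()] objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_tracked_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    utils::write.csv(data.frame(i = seq_len(nrow(fr$points)),
                                x = fr$points[, 1], y = fr$points[, 2]),
                     file.path(dir, sprintf("frame_%04d.csv", k)),
                     row.names = FALSE)
  }
  manifest <- list(n_frames = length(frames),
                   t = vapply(frames, `[[`, numeric(1), "t"),
                   pixel_size = frames[[1]]$pixel_size,
                   base = "first point",
                   units = "m")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read tracked frames written by [write_tracked_frames()]
#'
#' @param dir directory containing `frame_*.csv` and `manifest.json`.
#' @return A list of [tracked_frame()] objects.
#' @export
read_tracked_frames <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_.*\\.csv$",
                           full.names = TRUE))
  lapply(seq_along(files), function(k) {
    df <- utils::read.csv(files[k])
    tracked_frame(manifest$t[k], cbind(df$x, df$y), manifest$pixel_size)
  })
}
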