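# Shared test objects and independent oracles. Expensive computations
# (branch continuations) are cached per test run.

# reference conical whisker used throughout: 20 mm truncated cone,
# 30 um -> 1.5 um radii, E = 3 GPa, intrinsic parabola A = 0.02 / mm
ref_cone <- function() whisker_geometry(20, 30, 1.5, E_GPa = 3,
                                        A_per_mm = 0.02)

# homogeneous cylinder of the same length and base radius
ref_cyl <- function(r_um = 30) whisker_geometry(20, r_um, r_um, E_GPa = 3,
                                                A_per_mm = 0.02)

# thin pole placed for concave-backward contact about three quarters of
# the way out along the reference cone
ref_pole <- function() pole(0.25, 15.13, 4.29)

.ws_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ws_cache)) assign(key, expr, envir = .ws_cache)
  get(key, envir = .ws_cache)
}

cone_branch <- function() cached("cone_branch", {
  continue_branch(ref_cone(), base_pose(), ref_pole(), post_fold = TRUE)
})

cone_event <- function() cached("cone_event", {
  br <- cone_branch()
  br$event
})

cyl_pulloff <- function() cached("cyl_pulloff", {
  find_detachment(ref_cyl(), base_pose(), ref_pole())
})

# --- independent discrete-elastica relaxation oracle ---------------------
#
# Energy minimisation over a chain of n rigid segments spanning [0, s_obj]
# with the same bending stiffness profile EI(s) and intrinsic curvature as
# the whisker, the base clamped at the pose, and the chain end constrained
# to the pole surface by a stiff quadratic penalty. Entirely independent of
# the shooting solver: no ODE integration, plain L-BFGS on the segment
# angles with an analytic gradient.
elastica_relax <- function(geom, pose, pl, s_obj, side = "CB", n = 200,
                           mu = NULL) {
  h <- s_obj / n
  s_mid <- (seq_len(n) - 0.5) * h       # segment midpoints
  s_joint <- seq_len(n - 1) * h         # interior joints
  EIj <- geom$E * area_moment_at(geom, s_joint)
  EI0 <- geom$E * area_moment_at(geom, h / 4)
  kapj <- intrinsic_curvature(geom, s_joint)
  kap0 <- intrinsic_curvature(geom, h / 4)
  if (is.null(mu)) mu <- 1e5 * EI0 / geom$L_w^3
  cen <- c(pl$x_cen, pl$y_cen)
  usc <- h / EI0          # nondimensionalise the energy for the optimiser

  obj_with <- function(theta, theta_base) {
    # the first segment midpoint sits h/2 from the clamped base
    bend0 <- theta[1] - theta_base - h / 2 * kap0
    bendj <- diff(theta) - h * kapj
    U <- EI0 / h * bend0^2 + sum(EIj / (2 * h) * bendj^2)
    px <- pose$x0 + h * sum(cos(theta))
    py <- pose$y0 + h * sum(sin(theta))
    gap <- sqrt((px - cen[1])^2 + (py - cen[2])^2) - pl$r_pole
    usc * (U + mu / 2 * gap^2)
  }
  grad_with <- function(theta, theta_base) {
    bend0 <- theta[1] - theta_base - h / 2 * kap0
    bendj <- diff(theta) - h * kapj
    g <- numeric(n)
    g[1] <- 2 * EI0 / h * bend0
    g[-n] <- g[-n] - EIj / h * bendj
    g[-1] <- g[-1] + EIj / h * bendj
    px <- pose$x0 + h * sum(cos(theta))
    py <- pose$y0 + h * sum(sin(theta))
    dist <- sqrt((px - cen[1])^2 + (py - cen[2])^2)
    gap <- dist - pl$r_pole
    usc * (g + mu * gap / dist *
      ((px - cen[1]) * (-h * sin(theta)) + (py - cen[2]) * (h * cos(theta))))
  }

  # The penalty surface has a second (non-physical) basin with the chain
  # end on the far side of the pole. Reach the physical basin by homotopy:
  # relax first at the tangency pose (where the undeflected start is
  # feasible), then rotate the base toward the target pose in steps,
  # warm-starting each relaxation. Tangency comes from pure geometry
  # (initial_touch), keeping the oracle independent of the shooting path.
  # all tangency rotations of the base within +/- 1.5 rad, then keep the
  # one whose contact has the pole on the requested side (the side is an
  # input of the experiment - the pole placement - not a solver output)
  gap_at <- function(phi) vibrissa:::pole_gap(geom, pose, pl, phi)$gap
  phis <- seq(-1.5, 1.5, by = 0.005)
  gaps <- vapply(phis, gap_at, numeric(1))
  roots <- c()
  for (i in which(gaps[-1] * gaps[-length(gaps)] < 0))
    roots <- c(roots, stats::uniroot(gap_at, phis[c(i, i + 1)],
                                     tol = 1e-11)$root)
  side_of <- function(phi) {
    gt <- vibrissa:::pole_gap(geom, pose, pl, phi)
    p <- undeflected_point(gt$s, geom, gt$pose)
    cz <- cos(p$theta) * (pl$y_cen - p$y) - sin(p$theta) * (pl$x_cen - p$x)
    if (cz < 0) "CB" else "CF"
  }
  roots <- roots[vapply(roots, side_of, character(1)) == side]
  stopifnot(length(roots) >= 1)
  phi_touch <- roots[which.min(abs(roots))]
  th_path <- seq(pose$theta0 + phi_touch, pose$theta0, length.out = 8)
  pose_1 <- pose; pose_1$theta0 <- th_path[1]
  theta <- undeflected_point(s_mid, geom, pose_1)$theta
  op <- list(convergence = 0)
  for (k in seq_along(th_path)) {
    if (k > 1) theta <- theta + (th_path[k] - th_path[k - 1])
    op <- stats::optim(theta, obj_with, grad_with,
                       theta_base = th_path[k], method = "L-BFGS-B",
                       control = list(maxit = 10000, factr = 10, lmm = 20))
    theta <- op$par
  }
  x <- pose$x0 + h * cumsum(cos(theta))
  y <- pose$y0 + h * cumsum(sin(theta))
  list(s = seq_len(n) * h, x = c(pose$x0, x), y = c(pose$y0, y),
       convergence = op$convergence)
}

# linear interpolation of a solution curve at arclengths s
curve_at <- function(sol, s) {
  list(x = stats::approx(sol$curve$s, sol$curve$x, xout = s, rule = 2)$y,
       y = stats::approx(sol$curve$s, sol$curve$y, xout = s, rule = 2)$y)
}

# solve a branch point at a prescribed push angle from interpolated seeds
branch_solution_at <- function(br, theta_p, segment = c("stable", "unstable"),
                               settings = solver_settings()) {
  segment <- match.arg(segment)
  pts <- br$points
  idx <- if (segment == "stable") which(pts$stable) else which(!pts$stable)
  sgn <- if (br$direction == "CB") 1 else -1
  idx <- idx[order(pts$theta_p_deg[idx] * sgn)]
  v <- pts$theta_p_deg[idx] * sgn
  tgt <- abs(theta_p)
  stopifnot(tgt >= min(v), tgt <= max(v))
  seed <- list(
    F = stats::approx(v, pts$F[idx], xout = tgt, ties = "ordered")$y,
    s_obj = stats::approx(v, pts$s_obj[idx], xout = tgt, ties = "ordered")$y,
    theta_obj = deg2rad(stats::approx(v, pts$theta_obj_deg[idx], xout = tgt,
                                      ties = "ordered")$y),
    theta0 = deg2rad(stats::approx(v, pts$theta0_deg[idx], xout = tgt,
                                   ties = "ordered")$y))
  pose <- br$pose
  pose$theta0 <- seed$theta0
  solve_contact(br$geom, pose, br$pole, guess = seed, settings = settings,
                fixed = "pose", side = br$side_sign)
}

# --- shared expensive checks, computed once per test run ------------------

# small-deflection cantilever: straight homogeneous beam, tip-adjacent
# contact, light load; returns measured deflection and the closed form
cantilever_check <- function() cached("cantilever", {
  st <- whisker_geometry(20, 30, 30, A_per_mm = 0)
  pose <- base_pose()
  pl <- pole(0.25, 19, -0.25)          # tangent from below at x = 19 mm
  br <- continue_branch(st, pose, pl, post_fold = FALSE,
                        settings = solver_settings(step_deg = 0.1,
                                                   step_max_deg = 0.1),
                        max_steps = 12)
  cand <- br$points[br$points$F > 0, ]
  sol <- NULL
  for (i in rev(seq_len(nrow(cand)))) {
    pose_i <- base_pose(); pose_i$theta0 <- deg2rad(cand$theta0_deg[i])
    s <- solve_contact(st, pose_i, pl,
                       guess = list(F = cand$F[i],
                                    theta_obj = deg2rad(cand$theta_obj_deg[i]),
                                    s_obj = cand$s_obj[i]),
                       side = br$side_sign)
    end_x <- s$curve$x[nrow(s$curve)]; end_y <- s$curve$y[nrow(s$curve)]
    defl <- abs(-sin(s$theta0) * end_x + cos(s$theta0) * end_y)
    if (defl < 0.02 * st$L_w) { sol <- s; break }
  }
  stopifnot(!is.null(sol))
  end_x <- sol$curve$x[nrow(sol$curve)]; end_y <- sol$curve$y[nrow(sol$curve)]
  defl <- abs(-sin(sol$theta0) * end_x + cos(sol$theta0) * end_y)
  EI <- st$E * area_moment_at(st, 0)
  list(defl = defl, theory = sol$F * sol$s_obj^3 / (3 * EI))
})

# shooting solution vs discrete-elastica relaxation on random instances;
# returns the per-instance max shape deviation relative to L_w
elastica_check <- function() cached("elastica", {
  set.seed(11)
  dev_rel <- numeric(10)
  for (k in 1:10) {
    conical <- k %% 2 == 0
    g <- whisker_geometry(20, 30, if (conical) runif(1, 2, 10) else 30,
                          A_per_mm = runif(1, 0.005, 0.03))
    d <- runif(1, 0.5, 0.7) * g$L_w
    side <- sample(c("CB", "CF"), 1)
    pl <- place_pole_at_distance(g, base_pose(), d, 0.25e-3, side)
    br <- continue_branch(g, base_pose(), pl, post_fold = FALSE,
                          settings = solver_settings(step_deg = 0.5),
                          max_steps = 30)
    pts <- br$points
    i <- max(which(abs(pts$theta_p_deg) <= 6))
    pose_i <- base_pose(); pose_i$theta0 <- deg2rad(pts$theta0_deg[i])
    sol <- solve_contact(g, pose_i, pl,
                         guess = list(F = pts$F[i],
                                      theta_obj = deg2rad(pts$theta_obj_deg[i]),
                                      s_obj = pts$s_obj[i]),
                         side = br$side_sign)
    el <- elastica_relax(g, pose_i, pl, sol$s_obj, side = side, n = 200)
    bvp <- curve_at(sol, el$s)
    dev_rel[k] <- max(sqrt((el$x[-1] - bvp$x)^2 +
                           (el$y[-1] - bvp$y)^2)) / g$L_w
  }
  dev_rel
})

# pull-off angles of two homogeneous cylinders differing only in radius
radius_invariance_check <- function() cached("radius_inv", {
  pose <- base_pose()
  lapply(c(30, 60), function(r_um) {
    g <- ref_cyl(r_um)
    pl <- place_pole_at_distance(g, pose, 15.5e-3, 0.25e-3, "CB")
    find_detachment(g, pose, pl)
  })
})

# detachment curve of the reference cone over three object distances
cone_curve <- function() cached("cone_curve", {
  detachment_curve(ref_cone(), 0.25e-3, c(10e-3, 13e-3, 15.7e-3),
                   directions = c("CB", "CF"),
                   settings = solver_settings(step_deg = 0.5))
})

# effective-length recovery from slip events simulated at known length
length_recovery_check <- function() cached("length_rec", {
  true_g <- whisker_geometry(15.3, 33.5, 2, A_per_mm = 0.02,
                             x_vertex_mm = 2.2)
  pose <- base_pose()
  evs <- do.call(rbind, lapply(c(9e-3, 11e-3), function(d) {
    pl <- place_pole_at_distance(true_g, pose, d, 0.25e-3, "CB")
    ev <- find_detachment(true_g, pose, pl, solver_settings(step_deg = 0.5))
    data.frame(d = d, theta_p_deg = ev$theta_p_crit_deg)
  }))
  L_hat <- as.numeric(calibrate_effective_length(evs, true_g, 0.25e-3, pose))
  list(L_true = 15.3e-3, L_hat = L_hat, events = evs, geom = true_g)
})

# push-angle recovery from a synthetic tracked frame of a loaded whisker:
# noise-free error and rms error under sub-pixel (0.25 px) tracking noise
push_recovery_check <- function() cached("push_rec", {
  geom <- ref_cone()
  br <- cone_branch()
  sol <- branch_solution_at(br, 12, "stable")
  cu <- vibrissa:::ws_full_curve(geom, sol$pose, ref_pole(), sol$theta0,
                                 sol$F, sol$theta_obj, sol$s_obj,
                                 solver_settings(), n = 120)
  tp_true <- push_angle(sol$pose,
                        list(x_obj = sol$contact[["x_obj"]],
                             y_obj = sol$contact[["y_obj"]]), geom)
  fr <- tracked_frame(0, cbind(cu$x, cu$y), 0.031e-3)
  tp_est <- extract_push_angle(fr, geom, ref_pole())
  set.seed(17)
  tps <- replicate(40, {
    pts <- cbind(cu$x, cu$y) + matrix(rnorm(240, 0, 0.25 * 0.031e-3),
                                      ncol = 2)
    extract_push_angle(tracked_frame(0, pts, 0.031e-3), geom, ref_pole())
  })
  list(tp_true = tp_true, tp_est = tp_est, curve = cu, sol = sol,
       rms_noisy = sqrt(mean((tps - tp_true)^2)))
})

# scaled boundary residual of a solution re-integrated with the force
# perturbed by delta_rel of the characteristic force
resid_probe <- function(geom, sol, pl, delta_rel) {
  Fs <- vibrissa:::ws_force_scale(geom)
  out <- vibrissa:::ws_integrate(geom, pl, sol$pose$x0, sol$pose$y0,
                                 sol$theta0, sol$F + delta_rel * Fs,
                                 sol$theta_obj, sol$s_obj, sol$settings,
                                 side = sol$side)
  r <- vibrissa:::ws_residual_raw(out[nrow(out), ], pl, sol$side)
  c(r[1] / geom$L_w, r[2] / geom$L_w, r[3])
}

deg2rad <- vibrissa:::deg2rad
rad2deg <- vibrissa:::rad2deg
undeflected_point <- vibrissa:::undeflected_point
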