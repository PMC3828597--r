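test_that("base angle estimation: exact on collinear points, rotation-equivariant", {
  ang <- 30
  s <- seq(0, 11e-3, length.out = 12)
  pts <- cbind(s * cos(deg2rad(ang)), s * sin(deg2rad(ang)))
  fr <- tracked_frame(0, pts, 0.031e-3)
  expect_equal(estimate_base_angle(fr), 30, tolerance = 1e-9)

  expect_error(tracked_frame(0, pts[1:9, ], 0.031e-3), "insufficient")
  expect_error(tracked_frame(0, pts[c(1, 1, 2:11), ], 0.031e-3),
               "coincide")

  # rigid rotation of all points shifts the estimate by exactly alpha
  geom <- ref_cone()
  sh <- undeflected_shape(geom, base_pose(), n = 40)
  fr0 <- tracked_frame(0, cbind(sh$x, sh$y), 0.031e-3)
  a0 <- estimate_base_angle(fr0)
  for (alpha in c(-40, 15, 110)) {
    ca <- cos(deg2rad(alpha)); sa <- sin(deg2rad(alpha))
    rot <- cbind(ca * sh$x - sa * sh$y, sa * sh$x + ca * sh$y)
    fr <- tracked_frame(0, rot, 0.031e-3)
    da <- (estimate_base_angle(fr) - a0 - alpha) %% 360
    expect_lt(min(da, 360 - da), 1e-9)
  }

  # noise-free model curve: estimate matches the analytic tangent averaged
  # over the fitted span
  s_fit <- sh$s[5:10]
  ref_ang <- rad2deg(mean(undeflected_point(s_fit, geom, base_pose())$theta))
  expect_lt(abs(a0 - ref_ang), 0.2)
})

test_that("base angle estimator is robust to pixel noise", {
  geom <- ref_cone()
  sh <- undeflected_shape(geom, base_pose(), n = 40)
  set.seed(99)
  ests <- replicate(1000, {
    pts <- cbind(sh$x, sh$y) + matrix(rnorm(80, 0, 0.031e-3), ncol = 2)
    estimate_base_angle(tracked_frame(0, pts, 0.031e-3))
  })
  expect_lt(sd(ests), 1)
})

test_that("fixture generator is seeded, exact at zero noise, calibrated in noise", {
  geom <- ref_cone()
  proto <- sweep_protocol(f_hz = 0.2, amplitude_pp_deg = 17,
                          theta_center_deg = -5, phase0_deg = 90,
                          frame_rate = 8, duration_s = 2.5)
  traj <- galvo_trajectory(proto)
  spec0 <- fixture_spec(geom, ref_pole(), traj, n_points = 40,
                        pixel_noise_sd = 0, seed = 5)
  frames0 <- generate_fixture(spec0)
  sw <- attr(frames0, "sweep")
  expect_equal(length(frames0), nrow(traj))

  # zero noise: points sit on the model curve (free frame: the intrinsic
  # parabola)
  i_free <- which(!sw$frames$in_contact)[1]
  pose_i <- base_pose()
  pose_i$theta0 <- deg2rad(sw$frames$theta0_deg[i_free])
  p <- undeflected_point(seq(0, geom$L_w, length.out = 40), geom, pose_i)
  expect_lt(max(abs(frames0[[i_free]]$points[, 1] - p$x)), 1e-12)

  # contacting frame: distal end beyond the contact follows the free
  # continuation, and the whole polyline has arclength close to L_w
  i_c <- which(sw$frames$in_contact)[5]
  pts <- frames0[[i_c]]$points
  len <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
  expect_lt(abs(len - geom$L_w), 2e-3 * geom$L_w)

  # same seed: bit-identical; different seed: different noise
  spec1 <- fixture_spec(geom, ref_pole(), traj, n_points = 40,
                        pixel_noise_sd = 0.031e-3, seed = 5)
  fa <- generate_fixture(spec1)
  fb <- generate_fixture(spec1)
  expect_identical(fa[[3]]$points, fb[[3]]$points)
  spec2 <- fixture_spec(geom, ref_pole(), traj, n_points = 40,
                        pixel_noise_sd = 0.031e-3, seed = 6)
  fc <- generate_fixture(spec2)
  expect_false(identical(fa[[3]]$points, fc[[3]]$points))

  # noise calibration: rms point deviation within 5% of the nominal sd
  devs <- unlist(lapply(seq_along(fa), function(k)
    sqrt(rowSums((fa[[k]]$points - frames0[[k]]$points)^2))))
  rms_per_axis <- sqrt(mean(devs^2) / 2)
  expect_lt(abs(rms_per_axis - 0.031e-3), 0.05 * 0.031e-3)

  # frames survive a CSV round trip
  dir <- file.path(tempdir(), "vibrissa-frames")
  write_tracked_frames(fa, dir)
  back <- read_tracked_frames(dir)
  expect_equal(length(back), length(fa))
  expect_equal(back[[4]]$points, unname(fa[[4]]$points), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("push angle is recovered from fixtures and flips under mirroring", {
  geom <- ref_cone()
  pr <- push_recovery_check()
  cu <- pr$curve
  expect_lt(abs(pr$tp_est - pr$tp_true), 0.1)
  expect_gt(pr$tp_est, 0)    # CB contact
  expect_lt(pr$rms_noisy, 1)

  fr <- tracked_frame(0, cbind(cu$x, cu$y), 0.031e-3)
  # mirror the whole scene about the x-axis (concave-down imaging):
  # magnitude kept, sign flipped
  fr_m <- tracked_frame(0, cbind(cu$x, -cu$y), 0.031e-3)
  pole_m <- pole(0.25, ref_pole()$x_cen * 1e3, -ref_pole()$y_cen * 1e3)
  tp_m <- extract_push_angle(fr_m, geom, pole_m, mirror = TRUE)
  expect_equal(tp_m, -pr$tp_est, tolerance = 1e-6)

  # protraction convention overrides the curvature-based sign
  expect_equal(extract_push_angle(fr, geom, ref_pole(),
                                  sign_convention = "protraction",
                                  moving = "retraction"),
               -abs(pr$tp_est), tolerance = 1e-9)

  # undeflected whisker touching the pole: push angle at the noise floor
  it <- initial_touch(geom, base_pose(), ref_pole())
  pose_t <- base_pose(); pose_t$theta0 <- it$theta0_touch
  p <- undeflected_point(seq(0, geom$L_w, length.out = 120), geom, pose_t)
  fr0 <- tracked_frame(0, cbind(p$x, p$y), 0.031e-3)
  expect_lt(abs(extract_push_angle(fr0, geom, ref_pole())), 0.05)

  # frame with no point near the pole
  far <- tracked_frame(0, cbind(p$x, p$y + 5e-3), 0.031e-3)
  expect_error(extract_push_angle(far, geom, ref_pole()), "no contact")
})

test_that("projected arclength correction follows the cosine rule", {
  expect_equal(projected_arclength_correction(10e-3, 0)$factor, 1)
  corr <- projected_arclength_correction(10e-3, 14)
  expect_equal(corr$factor, 1 / cos(deg2rad(14)), tolerance = 1e-12)
  expect_equal(corr$factor, 1.031, tolerance = 1e-3)   # ~3% correction
  fac <- vapply(c(0, 5, 10, 20, 40), function(e)
    projected_arclength_correction(1, e)$factor, numeric(1))
  expect_true(all(diff(fac) > 0))
  expect_error(projected_arclength_correction(1, 90))
})

test_that("effective length is recovered from synthetic slip events", {
  # events generated from a known 15.3 mm whisker
  lr <- length_recovery_check()
  evs <- lr$events
  pose <- base_pose()
  L_hat <- lr$L_hat
  expect_lt(abs(L_hat - lr$L_true) / lr$L_true, 0.02)

  # scale consistency: scaling all lengths by k scales the answer by k
  k <- 1.25
  evs_k <- transform(evs, d = d * k)
  g_k <- whisker_geometry(15.3 * k, 33.5, 2, A_per_mm = 0.02 / k,
                          x_vertex_mm = 2.2 * k)
  L_k <- as.numeric(calibrate_effective_length(evs_k, g_k, 0.25e-3 * k, pose))
  expect_equal(L_k / L_hat, k, tolerance = 0.01)
})

test_that("a truncated whisker calibrates shorter than its untruncated twin", {
  pose <- base_pose()
  trunc_g <- whisker_geometry(12.5, 35, 8.5, A_per_mm = 0.02,
                              x_vertex_mm = 2.2)
  pl <- place_pole_at_distance(trunc_g, pose, 9e-3, 0.25e-3, "CB")
  ev <- find_detachment(trunc_g, pose, pl, solver_settings(step_deg = 0.5))
  evs <- data.frame(d = 9e-3, theta_p_deg = ev$theta_p_crit_deg)
  # fit the same events under a less truncated tip: the softer tip slips
  # earlier, so the fit compensates with a longer whisker - the truncated
  # whisker therefore calibrates shorter than its untruncated twin
  slim_g <- whisker_geometry(12.5, 35, 2, A_per_mm = 0.02,
                             x_vertex_mm = 2.2)
  L_slim <- as.numeric(calibrate_effective_length(evs, slim_g, 0.25e-3, pose))
  L_true <- as.numeric(calibrate_effective_length(evs, trunc_g, 0.25e-3, pose))
  expect_equal(L_true, 12.5e-3, tolerance = 0.02)
  expect_gt(L_slim, L_true)
})

test_that("end-to-end: slip events extracted from noisy fixtures land on the detachment curve", {
  # behaving-style session: 15.3 mm whisker, pole in the distal range,
  # drive pushed past the critical angle; tracks at quarter-pixel noise
  g <- whisker_geometry(15.3, 33.5, 2, A_per_mm = 0.02, x_vertex_mm = 2.2)
  pose <- base_pose()
  d <- 11e-3
  pl <- place_pole_at_distance(g, pose, d, 0.25e-3, "CB")
  ev <- find_detachment(g, pose, pl, solver_settings(step_deg = 0.5))
  expect_equal(ev$kind, "slip_off")

  touch_deg <- rad2deg(initial_touch(g, pose, pl)$theta0_touch)
  proto <- sweep_protocol(f_hz = 0.2, amplitude_pp_deg = 2 * (ev$theta_p_crit_deg + 8),
                          theta_center_deg = touch_deg + 4, phase0_deg = 90,
                          frame_rate = 64, duration_s = 2.5)
  traj <- galvo_trajectory(proto, pose)
  spec <- fixture_spec(g, pl, traj, n_points = 120,
                       pixel_noise_sd = 0.25 * 0.031e-3, seed = 3)
  frames <- generate_fixture(spec)
  sw <- attr(frames, "sweep")
  slips <- sw$events[sw$events$type == "slip_off", ]
  expect_equal(nrow(slips), 1)

  # last contacting frame before the slip: its extracted push angle must
  # sit within a degree (plus tracking noise) of the model's critical one
  i_last <- max(which(sw$frames$in_contact & sw$frames$t < slips$t))
  tp_hat <- extract_push_angle(frames[[i_last]], g, pl)
  expect_lt(abs(tp_hat - ev$theta_p_crit_deg), 1 + 0.5)
})
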