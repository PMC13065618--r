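test_that("kinetics constructor enforces its invariants", {
  expect_error(group_kinetics(arrest_rate = -1), ">= 0")
  expect_error(group_kinetics(rolling_speed_mean = 1200), "below the free-flow")
  expect_error(group_kinetics(capture_prob = 1.5), "capture_prob")
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  expect_error(simulation_config(duration_s = -5), "config error")
  expect_error(simulate_recording(group_kinetics(), duration_s = 0), "config error")
})

test_that("degenerate kinetics give constant-velocity tracks with zero acceleration", {
  k <- group_kinetics(free_flow_speed_sd = 0, rolling_speed_sd = 0,
                      jerk_rate = 0, arrest_rate = 0, entry_rate = 2)
  rec <- simulate_recording(k, duration_s = 20, frame_interval_s = 0.05, seed = 9)
  expect_gt(length(rec$tracks), 0)
  for (tr in rec$tracks) {
    expect_lt(diff(range(tr$vx)), 1e-6)
    expect_lt(max(abs(tr$ax)), 1e-4)
  }
})

test_that("the same seed reproduces a byte-identical recording", {
  k <- default_kinetics()$T2D$tnf
  r1 <- simulate_recording(k, duration_s = 15, frame_interval_s = 0.05, seed = 21)
  r2 <- simulate_recording(k, duration_s = 15, frame_interval_s = 0.05, seed = 21)
  f1 <- tempfile(); f2 <- tempfile()
  write_tracker_export(r1, f1); write_tracker_export(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- simulate_recording(k, duration_s = 15, frame_interval_s = 0.05, seed = 22)
  f3 <- tempfile(); write_tracker_export(r3, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("arrest frequency matches the closed-form absorption probability", {
  # deterministic rolling speed, so a cell needs a fixed number of frames to
  # cross the window; per-frame arrest probability p gives
  # P(arrest) = 1 - (1 - p)^K for cells whose exposure is not truncated
  dt <- 0.05; v <- 400; wx <- 600
  k <- group_kinetics(rolling_speed_mean = v, rolling_speed_sd = 0,
                      jerk_rate = 0, arrest_rate = 1, release_rate = 0,
                      entry_rate = 20, capture_prob = 1)
  rec <- simulate_recording(k, duration_s = 60, frame_interval_s = dt, seed = 14)
  K <- ceiling(wx / (v * dt))
  p_frame <- 1 * dt
  p_closed <- 1 - (1 - p_frame)^K
  full <- Filter(function(tr) tr$t[1] < 60 - (K * dt + 35), rec$tracks)
  arrested <- vapply(full, function(tr) "arrest" %in% tr$states, TRUE)
  expect_gt(length(full), 300)
  expect_equal(mean(arrested), p_closed, tolerance = 0.06)
  # with release_rate = 0 those cells stay arrested to the end: adhesion
  # counts them all
  cp <- classical_parameters(rec, seed = 3)
  expect_gt(cp$adhesion, 0)
})

test_that("every in-field interval carries exactly one motion state", {
  rec <- simulate_recording(default_kinetics()$T2D$basal, duration_s = 20,
                            frame_interval_s = 0.05, seed = 31)
  for (tr in rec$tracks) {
    expect_length(tr$states, length(tr$t) - 1L)
    expect_true(all(tr$states %in% c("free", "rolling", "arrest")))
  }
  # occupancy conservation at sampled frames
  times <- seq(0.5, 19.5, by = 0.7)
  for (tt in times) {
    in_field <- sum(vapply(rec$tracks, function(tr)
      tr$t[1] <= tt && tt < tr$t[length(tr$t)], TRUE))
    by_state <- sum(vapply(rec$tracks, function(tr) {
      i <- findInterval(tt, tr$t)
      as.integer(i >= 1 && i < length(tr$t))
    }, 0L))
    expect_equal(by_state, in_field)
  }
})

test_that("mean free-flow velocity converges to the configured mean", {
  k <- group_kinetics(capture_prob = 0, entry_rate = 40)
  rec <- simulate_recording(k, duration_s = 30, frame_interval_s = 0.05, seed = 17)
  v <- unlist(lapply(rec$tracks, function(tr) tr$vx[tr$states == "free"]))
  expect_gt(length(v), 1e4)
  expect_equal(mean(v), 1000, tolerance = 0.01)
})

test_that("cohort assembly attaches labels, features and copula biomarkers", {
  spec <- list(list(name = "il8", mean = 50, sd = 10, rho = 0.7,
                    descriptor = "v_ave"))
  cfg <- simulation_config(n_per_group = 10, duration_s = 40,
                           frame_interval_s = 0.05, conditions = "basal",
                           biomarker_spec = spec, seed = 33)
  sim <- suppressMessages(simulate_cohort(cfg))
  coh <- sim$cohort
  expect_equal(nrow(coh), 30)
  expect_true(all(feature_names() %in% names(coh)))
  expect_true(all(c("rolling_velocity", "rolling_flux", "adhesion", "il8") %in% names(coh)))
  expect_false(any(duplicated(coh[, c("individual_id", "tnf")])))
  # within-group sample correlation near the target (sampling error bound)
  r <- mean(vapply(unique(coh$group), function(g) {
    sub <- coh[coh$group == g, ]
    cor(sub$il8, sub$v_ave)
  }, 0))
  expect_equal(r, 0.7, tolerance = 0.25)
  expect_error(simulate_cohort(simulation_config(
    biomarker_spec = list(list(name = "b", mean = 0, sd = 1, rho = 0.5,
                               descriptor = "nope")),
    n_per_group = 2, duration_s = 5, conditions = "basal")), "unknown descriptor")
})

test_that("rendering and re-tracking recovers trajectories from synthetic frames", {
  k <- group_kinetics(rolling_speed_mean = 300, rolling_speed_sd = 50,
                      jerk_rate = 0, arrest_rate = 0, entry_rate = 0.5,
                      capture_prob = 1)
  rec <- simulate_recording(k, duration_s = 8, frame_interval_s = 0.1, seed = 5)
  ret <- render_and_track(rec, noise_sd = 0, psf_sigma_um = 4, seed = 1, px_um = 1)
  expect_gt(length(ret$tracks), 0)
  v_in <- novel_features(rec)["v_ave"]
  v_out <- novel_features(ret)["v_ave"]
  expect_equal(unname(v_out), unname(v_in), tolerance = 0.02)

  # blank recording renders to an empty result without crashing
  blank <- field_recording("b", "Healthy", FALSE, 1,
                           calibration_spec(frame_interval_s = 0.1), list())
  ret0 <- render_and_track(blank, noise_sd = 0, seed = 1)
  expect_length(ret0$tracks, 0)

  # two cells crossing within the gate log at least one ambiguity
  t <- 0.1 * (0:20)
  a <- lk_track("a", t, 100 + 200 * t, rep(240, 21))
  b <- lk_track("b", t, 150 + 150 * t, rep(244, 21))
  cross <- field_recording("x", "Healthy", FALSE, 2,
                           calibration_spec(frame_interval_s = 0.1),
                           list(compute_kinematics(a), compute_kinematics(b)))
  ret2 <- render_and_track(cross, noise_sd = 0, seed = 1)
  expect_gt(attr(ret2, "n_ambiguities"), 0)
})
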