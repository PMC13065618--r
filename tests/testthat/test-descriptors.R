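test_that("rolling events follow the frame-to-frame sign rule", {
  mk <- function(v) {
    # build a track whose velocity series equals v exactly (binary-exact dt)
    x <- cumsum(c(0, v * 0.25))
    compute_kinematics(lk_track("r", 0.25 * (0:length(v)), x))
  }
  expect_equal(rolling_event_counts(mk(c(100, 200, 300)))[c("n_pos", "n_neg")],
               list(n_pos = 2L, n_neg = 0L))
  expect_equal(rolling_event_counts(mk(rep(250, 4)))[c("n_pos", "n_neg")],
               list(n_pos = 0L, n_neg = 0L))
  expect_equal(rolling_event_counts(mk(c(100, 300, 100, 300, 100)))[c("n_pos", "n_neg")],
               list(n_pos = 2L, n_neg = 2L))
  # dead band suppresses small changes
  expect_equal(rolling_event_counts(mk(c(100, 104, 100)), epsilon_um_s = 5)$n_pos, 0L)
  short <- rolling_event_counts(lk_track("s", c(0, 0.1), c(0, 1)))
  expect_true(short$short_track)
  expect_equal(short$n_pos, 0L)
})

test_that("degenerate recordings yield the expected feature values", {
  one <- make_recording(list(constant_track("a", 300)))
  f <- novel_features(one)
  expect_equal(unname(f["v_ave"]), 300)
  expect_equal(unname(f["v_med"]), 300)
  expect_equal(unname(f["v_0_500"]), 300)
  expect_equal(unname(f[c("N_v_0_500", "N_v_500_1000", "N_v_1000_1500", "N_v_1500_inf")]),
               c(1, 0, 0, 0))
  expect_equal(unname(f["a_ave"]), 0)
  expect_equal(unname(f[c("R_pos", "R_neg")]), c(0, 0))
  expect_true(is.na(f["R_ratio"]))
  expect_true(is.na(f["s_vx"]))

  two <- make_recording(list(constant_track("a", 300), constant_track("b", 700)))
  f2 <- novel_features(two)
  expect_equal(unname(f2["v_ave"]), 500)
  expect_equal(unname(f2[c("N_v_0_500", "N_v_500_1000")]), c(1, 1))
  expect_equal(unname(f2["prod_v_0_500_x_500_1000"]), 300 * 700)
  expect_error(novel_features(make_recording(list(lk_track("s", c(0, .1), c(0, 1))))),
               "no usable tracks")
})

test_that("a value on a bin edge belongs to the upper bin and binning is exhaustive", {
  edge <- make_recording(list(constant_track("e", 500)))
  f <- novel_features(edge)
  expect_equal(unname(f["N_v_500_1000"]), 1)
  expect_equal(unname(f["N_v_0_500"]), 0)
  # property: every finite value lands in exactly one of the 4 bins
  set.seed(3)
  v <- c(runif(200, -100, 3000), 0, 500, 1000, 1500, 1e7)
  b <- leukoflow:::.assign_bin(v, c(0, 500, 1000, 1500, Inf))
  expect_true(all(b %in% 1:4))
  expect_equal(b[v == 500][1], 2L)
  expect_equal(b[v == 1500][1], 4L)
})

test_that("feature panel matches an independent re-implementation on simulated data", {
  rec <- simulate_recording(default_kinetics()$T2D$basal, duration_s = 40,
                            frame_interval_s = 0.05, seed = 12,
                            calibration = calibration_spec(frame_interval_s = 0.05))
  f <- novel_features(rec)
  expected <- oracle_features(rec)  # independent loop-based route
  expect_equal(unclass(f)[names(expected)], expected, tolerance = 1e-9)
})

test_that("descriptor invariants: conservation, product identity, position scaling", {
  rec <- simulate_recording(default_kinetics()$T1D$basal, duration_s = 30,
                            frame_interval_s = 0.05, seed = 8)
  f <- novel_features(rec)
  n <- attr(f, "n_tracks")
  expect_equal(sum(f[c("N_v_0_500", "N_v_500_1000", "N_v_1000_1500", "N_v_1500_inf")]), n)
  expect_equal(sum(f[c("N_a_minf_m5000", "N_a_m5000_0", "N_a_0_5000", "N_a_5000_inf")]), n)
  expect_equal(unname(f["prod_v_0_500_x_500_1000"]),
               unname(f["v_0_500"] * f["v_500_1000"]))
  expect_equal(unname(f["prod_a_m5000_0_x_0_5000"]),
               unname(f["a_m5000_0"] * f["a_0_5000"]))

  # scale positions; bins are scale-dependent so widen edges alongside
  c_ <- 2
  scaled <- rec
  scaled$tracks <- lapply(rec$tracks, function(tr) {
    tr$x <- c_ * tr$x
    compute_kinematics(lk_track(tr$track_id, tr$t, tr$x, tr$y))
  })
  scaled$calibration$window_x_um <- c_ * rec$calibration$window_x_um
  bs <- bin_scheme(velocity_edges = c_ * c(0, 500, 1000, 1500, Inf),
                   acceleration_edges = c_ * c(-Inf, -5000, 0, 5000, Inf))
  fs <- novel_features(scaled, bins = bs)
  expect_equal(unname(fs["v_ave"]), c_ * unname(f["v_ave"]))
  expect_equal(unname(fs["a_ave"]), c_ * unname(f["a_ave"]))
  expect_equal(unname(fs["s_vx"]), c_ * unname(f["s_vx"]))
  expect_equal(unname(fs["R_pos"]), unname(f["R_pos"]))
  expect_equal(unname(fs["N_v_0_500"]), unname(f["N_v_0_500"]))
  expect_equal(unname(fs["prod_v_0_500_x_500_1000"]),
               c_^2 * unname(f["prod_v_0_500_x_500_1000"]))
})

test_that("classical parameters implement the timing, dwell and extrapolation rules", {
  # one cell crossing the central 100 um segment in 0.5 s
  dt <- 0.05
  t <- dt * (0:40)
  cross <- compute_kinematics(lk_track("c", t, 200 * t + 150))
  rec <- make_recording(list(cross), duration_s = 2, frame_interval_s = dt)
  cp <- classical_parameters(rec, seed = 2)
  expect_equal(cp$rolling_velocity, 200, tolerance = 0.05)

  # no track crossing the segment: rolling velocity flagged missing
  stat_tracks <- lapply(1:3, function(i)
    compute_kinematics(lk_track(paste0("s", i), seq(0, 35, by = 0.5),
                                rep(c(100, 300, 500)[i], 71),
                                rep(c(100, 240, 380)[i], 71))))
  rec2 <- make_recording(stat_tracks, duration_s = 35, frame_interval_s = 0.5)
  cp2 <- classical_parameters(rec2, seed = 2)
  expect_true(is.na(cp2$rolling_velocity))
  # 3 cells stationary >= 30 s in the 0.288 mm2 field, extrapolated to 8.77 mm2
  expect_equal(cp2$adhesion, 3 * 8.77 / 0.288, tolerance = 1e-6)

  # simulator without arrest produces no adherent cells
  rec3 <- simulate_recording(group_kinetics(arrest_rate = 0, entry_rate = 1),
                             duration_s = 40, frame_interval_s = 0.05, seed = 4)
  expect_equal(classical_parameters(rec3, seed = 1)$adhesion, 0)
  expect_error(classical_parameters(rec, field_frac = 0), "zero-area")
})

test_that("feature dictionary covers the full panel with matching names", {
  dict <- feature_dictionary()
  expect_true(all(feature_names() %in% dict$name))
  expect_true(all(c("rolling_velocity", "rolling_flux", "adhesion") %in% dict$name))
  expect_equal(length(feature_names()), 45L)
})
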