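# in-code fixtures shared across test files

# track with given constant velocity (um/s) on a uniform frame grid;
# dt defaults to a binary-exact value so constant speeds stay exactly constant
constant_track <- function(id, v, n = 5, dt = 0.25, t0 = 0, x0 = 0) {
  t <- t0 + dt * (0:(n - 1))
  compute_kinematics(lk_track(id, t, x0 + v * (t - t0)))
}

# recording wrapping a list of tracks
make_recording <- function(tracks, duration_s = NULL, group = "Healthy",
                           tnf = FALSE, frame_interval_s = 0.1) {
  if (is.null(duration_s))
    duration_s <- max(vapply(tracks, function(tr) max(tr$t), 0))
  field_recording("fix", group, tnf, max(duration_s, 1e-6),
                  calibration_spec(frame_interval_s = frame_interval_s), tracks)
}

# small simulated cohort used by several statistics tests
quick_cohort <- function(seed = 1, n_per_group = 6, duration_s = 40,
                         conditions = "basal") {
  cfg <- simulation_config(n_per_group = n_per_group, duration_s = duration_s,
                           frame_interval_s = 0.05, conditions = conditions,
                           seed = seed)
  suppressMessages(simulate_cohort(cfg))
}

# random multi-group design matrix for discriminant tests
random_design <- function(n_per_group, p, g = length(n_per_group),
                          shift = NULL, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(paste0("G", seq_len(g)), times = n_per_group))
  X <- matrix(rnorm(sum(n_per_group) * p), ncol = p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  if (!is.null(shift))
    for (k in seq_len(g)) {
      rows <- labels == paste0("G", k)
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, shift[k, ], `+`)
    }
  list(X = X, labels = labels)
}
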