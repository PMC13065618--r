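#' Kinetic parameters of one simulated group
#'
#' Describes the stochastic motion of leukocytes from one clinical condition
#' in the simulated flow chamber. Cells enter the field as a Poisson process
#' and either transit in free flow or are captured into rolling; rolling
#' cells can arrest on the endothelium and be released again, and experience
#' jerk events -- transient, sign-alternating velocity steps reflecting the
#' rapid make-and-break of adhesion bonds.
#'
#' @param free_flow_speed_mean,free_flow_speed_sd Free-flow velocity
#'   distribution, micrometres per second.
#' @param rolling_speed_mean,rolling_speed_sd Rolling velocity distribution,
#'   micrometres per second; the rolling mean must be below the free-flow
#'   mean.
#' @param jerk_rate Expected jerk events per second while rolling.
#' @param jerk_speed Magnitude of the velocity step injected by a jerk event
#'   (um/s); successive events alternate in sign.
#' @param arrest_rate Per-second probability intensity of a rolling cell
#'   arresting.
#' @param release_rate Per-second probability intensity of an arrested cell
#'   resuming rolling.
#' @param entry_rate New cells entering the field per second.
#' @param capture_prob Probability that an entering cell is captured into
#'   rolling (otherwise it transits the window in free flow).
#' @return An object of class \code{group_kinetics}.
#' @export
group_kinetics <- function(free_flow_speed_mean = 1000, free_flow_speed_sd = 100,
                           rolling_speed_mean = 400, rolling_speed_sd = 120,
                           jerk_rate = 1, jerk_speed = 300,
                           arrest_rate = 0.02, release_rate = 0.05,
                           entry_rate = 0.5, capture_prob = 0.5) {
  rates <- c(jerk_rate, arrest_rate, release_rate, entry_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (free_flow_speed_mean <= 0 || rolling_speed_mean <= 0)
    stop("speed means must be > 0", call. = FALSE)
  if (rolling_speed_mean >= free_flow_speed_mean)
    stop("rolling mean speed must be below the free-flow mean", call. = FALSE)
  if (capture_prob < 0 || capture_prob > 1)
    stop("capture_prob must lie in [0, 1]", call. = FALSE)
  structure(list(free_flow_speed_mean = free_flow_speed_mean,
                 free_flow_speed_sd = free_flow_speed_sd,
                 rolling_speed_mean = rolling_speed_mean,
                 rolling_speed_sd = rolling_speed_sd,
                 jerk_rate = jerk_rate, jerk_speed = jerk_speed,
                 arrest_rate = arrest_rate, release_rate = release_rate,
                 entry_rate = entry_rate, capture_prob = capture_prob),
            class = "group_kinetics")
}

#' Default kinetic presets for the six simulated conditions
#'
#' Scenario parameters for Healthy, T1D and T2D groups with and without
#' TNF-alpha activation: Healthy cells roll fast and rarely arrest, T1D
#' cells roll slowly with frequent jerk events, and T2D cells roll at
#' intermediate speed but arrest often. TNF-alpha activation slows rolling,
#' doubles the arrest intensity and increases capture, for every group.
#' These are qualitative scenario settings for method validation, not
#' estimates of any clinical distribution.
#'
#' @return A nested list \code{presets[[group]][[condition]]} with groups
#'   \code{Healthy}, \code{T1D}, \code{T2D} and conditions \code{basal},
#'   \code{tnf}, each a \code{\link{group_kinetics}}.
#' @export
default_kinetics <- function() {
  basal <- list(
    Healthy = group_kinetics(rolling_speed_mean = 600, rolling_speed_sd = 150,
                             jerk_rate = 0.5, arrest_rate = 0.01,
                             release_rate = 0.05, entry_rate = 0.4,
                             capture_prob = 0.5),
    T1D = group_kinetics(rolling_speed_mean = 200, rolling_speed_sd = 80,
                         jerk_rate = 2, arrest_rate = 0.02,
                         release_rate = 0.05, entry_rate = 0.5,
                         capture_prob = 0.7),
    T2D = group_kinetics(rolling_speed_mean = 400, rolling_speed_sd = 120,
                         jerk_rate = 1, arrest_rate = 0.08,
                         release_rate = 0.02, entry_rate = 0.5,
                         capture_prob = 0.6)
  )
  lapply(basal, function(k) {
    tnf <- k
    tnf$rolling_speed_mean <- k$rolling_speed_mean * 0.7
    tnf$arrest_rate <- k$arrest_rate * 2
    tnf$capture_prob <- min(0.95, k$capture_prob + 0.1)
    tnf$entry_rate <- k$entry_rate * 1.2
    list(basal = k, tnf = do.call(group_kinetics, unclass(tnf)))
  })
}

#' Cohort simulation configuration
#'
#' @param kinetics Nested preset list as returned by
#'   \code{\link{default_kinetics}} (\code{[[group]][[condition]]}).
#' @param n_per_group Individuals per clinical group (>= 2).
#' @param duration_s Recording length in seconds (assay default 300).
#' @param frame_interval_s Frame interval in seconds (default 0.033).
#' @param conditions Which endothelial conditions to simulate per
#'   individual: subset of \code{c("basal", "tnf")}.
#' @param biomarker_spec Optional list of biomarker definitions, each a list
#'   with elements \code{name}, \code{mean} (single value or named
#'   per-group vector), \code{sd}, \code{rho} (target correlation,
#'   |rho| < 1) and \code{descriptor} (feature column it correlates with).
#' @param calibration A \code{\link{calibration_spec}}.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(kinetics = default_kinetics(), n_per_group = 10,
                              duration_s = 300, frame_interval_s = 0.033,
                              conditions = c("basal", "tnf"),
                              biomarker_spec = list(),
                              calibration = calibration_spec(frame_interval_s = frame_interval_s),
                              seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (duration_s <= 0 || frame_interval_s <= 0)
    stop("config error: duration and frame interval must be positive", call. = FALSE)
  conditions <- match.arg(conditions, c("basal", "tnf"), several.ok = TRUE)
  for (bm in biomarker_spec) {
    stopifnot(is.list(bm), !is.null(bm$name), !is.null(bm$rho),
              !is.null(bm$descriptor))
    if (abs(bm$rho) >= 1) stop("|target correlation| must be < 1", call. = FALSE)
  }
  structure(list(kinetics = kinetics, n_per_group = n_per_group,
                 duration_s = duration_s, frame_interval_s = frame_interval_s,
                 conditions = conditions, biomarker_spec = biomarker_spec,
                 calibration = calibration, seed = as.integer(seed)),
            class = "simulation_config")
}

# run the RNG at a given seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one flow-chamber recording
#'
#' Cells enter the 600 x 480 um field at Poisson times. An entering cell is
#' captured into rolling with probability \code{capture_prob}; otherwise it
#' transits in free flow. Rolling cells arrest with per-second intensity
#' \code{arrest_rate} and are released with intensity \code{release_rate}
#' (a three-state chain: free flow -> rolling <-> arrest). Per-frame
#' displacements are drawn from the current state's velocity distribution;
#' while rolling, jerk events at rate \code{jerk_rate} add a velocity step
#' of magnitude \code{jerk_speed} with alternating sign. A track ends when
#' the cell leaves the window or the recording ends. Identical seeds give
#' identical recordings.
#'
#' @param kinetics A \code{\link{group_kinetics}}.
#' @param duration_s,frame_interval_s Recording length and frame interval.
#' @param seed Integer seed.
#' @param individual_id,group,tnf Metadata for the recording.
#' @param calibration A \code{\link{calibration_spec}}.
#' @return A \code{\link{field_recording}}; each track carries its
#'   per-interval motion state in \code{$states}
#'   (\code{"free"}/\code{"rolling"}/\code{"arrest"}).
#' @export
simulate_recording <- function(kinetics, duration_s = 300,
                               frame_interval_s = 0.033, seed = 1L,
                               individual_id = "sim", group = "Healthy",
                               tnf = FALSE,
                               calibration = calibration_spec(frame_interval_s = frame_interval_s)) {
  stopifnot(inherits(kinetics, "group_kinetics"))
  if (duration_s <= 0 || frame_interval_s <= 0)
    stop("config error: duration and frame interval must be positive", call. = FALSE)
  dt <- frame_interval_s
  wx <- calibration$window_x_um
  wy <- calibration$window_y_um

  tracks <- with_seed(seed, {
    n_cells <- stats::rpois(1, kinetics$entry_rate * duration_s)
    if (n_cells == 0) list() else {
      # entries snapped to the frame grid
      entry <- floor(sort(stats::runif(n_cells, 0, duration_s)) / dt) * dt
      lapply(seq_len(n_cells), function(i)
        .simulate_cell(kinetics, entry[i], duration_s, dt, wx, wy,
                       sprintf("cell%04d", i)))
    }
  })
  tracks <- Filter(function(tr) length(tr$t) >= 2, tracks)
  tracks <- lapply(tracks, compute_kinematics)
  field_recording(individual_id, group, tnf, duration_s, calibration, tracks)
}

.simulate_cell <- function(k, t0, duration_s, dt, wx, wy, id) {
  max_frames <- floor((duration_s - t0) / dt + 1e-9)
  if (max_frames < 1) return(lk_track(id, t0, 0))
  captured <- stats::runif(1) < k$capture_prob
  state <- if (captured) "rolling" else "free"
  jerk_sign <- 1
  v <- numeric(0); states <- character(0)
  remaining <- max_frames
  repeat {
    if (remaining <= 0) break
    if (state == "free") {
      # free-flowing cells never capture mid-window; they transit
      m <- remaining
      vi <- stats::rnorm(m, k$free_flow_speed_mean, k$free_flow_speed_sd)
      nxt <- NULL
    } else if (state == "rolling") {
      p_out <- min(1, k$arrest_rate * dt)
      m <- if (p_out > 0) min(remaining, stats::rgeom(1, p_out) + 1L) else remaining
      vi <- stats::rnorm(m, k$rolling_speed_mean, k$rolling_speed_sd)
      p_jerk <- min(1, k$jerk_rate * dt)
      if (p_jerk > 0) {
        ev <- which(stats::runif(m) < p_jerk)
        for (j in ev) {
          vi[j] <- vi[j] + jerk_sign * k$jerk_speed
          jerk_sign <- -jerk_sign
        }
      }
      nxt <- "arrest"
    } else { # arrest
      p_out <- min(1, k$release_rate * dt)
      m <- if (p_out > 0) min(remaining, stats::rgeom(1, p_out) + 1L) else remaining
      vi <- rep(0, m)
      nxt <- "rolling"
    }
    v <- c(v, vi); states <- c(states, rep(state, m))
    remaining <- remaining - m
    if (is.null(nxt) || remaining <= 0) break
    state <- nxt
  }
  x <- cumsum(v * dt)
  inside <- which(x <= wx)
  keep <- if (length(inside)) max(inside) else 0L
  x <- c(0, x[seq_len(keep)])
  t <- t0 + dt * (0:keep)
  tr <- lk_track(id, t, x, rep(stats::runif(1, 0, wy), keep + 1L))
  tr$states <- states[seq_len(keep)]
  tr
}

#' Simulate a labelled cohort with descriptors and biomarkers
#'
#' Simulates one recording per individual and condition using the group
#' presets in the configuration, extracts the full hydrodynamic feature
#' vector and the classical parameters from each recording, and assembles
#' the per-individual cohort table the group statistics and discriminant
#' analysis consume. Optional biomarker columns are generated per individual
#' by a Gaussian-copula construction: within each clinical group the named
#' descriptor is standardized, mixed with independent Gaussian noise as
#' \code{rho * z + sqrt(1 - rho^2) * noise}, and rescaled to the requested
#' mean and standard deviation, so the within-group correlation to the
#' descriptor approaches \code{rho}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{cohort} (data.frame: identifiers, labels, the
#'   three classical parameters, the 45 descriptors, biomarkers) and
#'   \code{recordings} (named list of \code{field_recording}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  known <- c(feature_names(), "rolling_velocity", "rolling_flux", "adhesion")
  for (bm in config$biomarker_spec)
    if (!bm$descriptor %in% known)
      stop("config error: unknown descriptor in biomarker_spec: ",
           bm$descriptor, call. = FALSE)
  groups <- names(config$kinetics)
  rows <- list(); recordings <- list()
  counter <- 0L
  for (g in groups) {
    for (i in seq_len(config$n_per_group)) {
      iid <- sprintf("%s%02d", substr(g, 1, 2), i)
      for (cond in config$conditions) {
        counter <- counter + 1L
        seed_i <- (config$seed + 7919L * counter) %% .Machine$integer.max
        rec <- simulate_recording(config$kinetics[[g]][[cond]],
                                  duration_s = config$duration_s,
                                  frame_interval_s = config$frame_interval_s,
                                  seed = seed_i, individual_id = iid,
                                  group = g, tnf = (cond == "tnf"),
                                  calibration = config$calibration)
        recordings[[paste(iid, cond, sep = "_")]] <- rec
        feats <- novel_features(rec)
        cls <- classical_parameters(rec, seed = seed_i)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = iid, group = g, tnf = (cond == "tnf"),
          rolling_velocity = cls$rolling_velocity,
          rolling_flux = cls$rolling_flux,
          adhesion = cls$adhesion,
          as.list(unclass(feats)[feature_names()]),
          check.names = FALSE)
      }
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  if (length(config$biomarker_spec))
    cohort <- with_seed(config$seed + 104729L,
                        .add_biomarkers(cohort, config$biomarker_spec))
  list(cohort = cohort, recordings = recordings)
}

# biomarkers are per individual (serum assay): built from the individual's
# basal-condition descriptor and replicated across that individual's rows
.add_biomarkers <- function(cohort, spec) {
  base <- cohort[!cohort$tnf, , drop = FALSE]
  if (!nrow(base)) base <- cohort[!duplicated(cohort$individual_id), , drop = FALSE]
  for (bm in spec) {
    if (!bm$descriptor %in% names(cohort))
      stop("config error: unknown descriptor in biomarker_spec: ",
           bm$descriptor, call. = FALSE)
    val <- stats::setNames(rep(NA_real_, nrow(base)), base$individual_id)
    for (g in unique(base$group)) {
      idx <- which(base$group == g)
      d <- base[[bm$descriptor]][idx]
      z <- if (stats::sd(d, na.rm = TRUE) > 0) as.numeric(scale(d)) else rep(0, length(d))
      z[is.na(z)] <- 0
      b <- bm$rho * z + sqrt(1 - bm$rho^2) * stats::rnorm(length(idx))
      mu <- if (length(bm$mean) > 1) bm$mean[[g]] else bm$mean
      val[idx] <- mu + (if (is.null(bm$sd)) 1 else bm$sd) * b
    }
    cohort[[bm$name]] <- as.numeric(val[cohort$individual_id])
  }
  cohort
}
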