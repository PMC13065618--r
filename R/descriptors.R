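#' Velocity and acceleration binning scheme
#'
#' Half-open bins used for the per-range descriptors: a value exactly on an
#' edge belongs to the upper bin. Velocities (um/s) are binned by the mean
#' absolute per-frame velocity of each cell, accelerations (um/s^2) by the
#' mean signed per-frame acceleration, since the acceleration ranges span
#' negative values.
#'
#' @param velocity_edges Increasing edges; default
#'   \code{c(0, 500, 1000, 1500, Inf)}.
#' @param acceleration_edges Increasing edges; default
#'   \code{c(-Inf, -5000, 0, 5000, Inf)}.
#' @return An object of class \code{bin_scheme}.
#' @export
bin_scheme <- function(velocity_edges = c(0, 500, 1000, 1500, Inf),
                       acceleration_edges = c(-Inf, -5000, 0, 5000, Inf)) {
  if (any(diff(velocity_edges) <= 0) || any(diff(acceleration_edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (length(velocity_edges) != 5 || length(acceleration_edges) != 5)
    stop("exactly 4 velocity and 4 acceleration bins are expected", call. = FALSE)
  structure(list(velocity_edges = velocity_edges,
                 acceleration_edges = acceleration_edges),
            class = "bin_scheme")
}

# bin assignment, half-open [edge_i, edge_{i+1}); values on an edge go up
.assign_bin <- function(v, edges) {
  b <- findInterval(v, edges[-length(edges)])
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Count positive and negative rolling events of a track
#'
#' A rolling event is a frame-to-frame change of the velocity series:
#' an increase beyond \code{epsilon} counts as a positive rolling
#' (acceleration, detachment-like), a decrease beyond \code{epsilon} as a
#' negative rolling (deceleration, adhesion-like). Events are counted
#' photogram by photogram along the whole track.
#'
#' @param track An \code{lk_track} with kinematics computed.
#' @param epsilon_um_s Dead band on the velocity change (default 0).
#' @return A list with \code{n_pos}, \code{n_neg} and \code{short_track}
#'   (TRUE when the track has fewer than 3 points and no events can be
#'   counted).
#' @export
rolling_event_counts <- function(track, epsilon_um_s = 0) {
  stopifnot(inherits(track, "lk_track"))
  if (length(track$t) < 3)
    return(list(n_pos = 0L, n_neg = 0L, short_track = TRUE))
  if (is.null(track$vx)) track <- compute_kinematics(track)
  dv <- diff(track$vx)
  list(n_pos = sum(dv > epsilon_um_s),
       n_neg = sum(dv < -epsilon_um_s),
       short_track = FALSE)
}

#' Canonical column order of the 45-descriptor panel
#'
#' @return Character vector of the 45 descriptor column names, in the order
#'   used by \code{\link{novel_features}} and the cohort tables.
#' @export
feature_names <- function() {
  c("v_ave", "v_med", "v_0_500", "v_500_1000", "v_1000_1500", "v_1500_inf",
    "a_ave", "a_med", "ratio_va_ave", "ratio_va_med", "prod_va_ave",
    "prod_va_med", "a_minf_m5000", "a_m5000_0", "a_0_5000", "a_5000_inf",
    "R_pos", "R_neg", "R_ratio",
    "s_vx", "s_ax", "ratio_s", "prod_s", "ratio_vave_svx", "ratio_aave_sax",
    "prod_v_0_500_x_500_1000", "prod_v_0_500_x_1000_1500",
    "prod_v_0_500_x_1500_inf", "prod_v_500_1000_x_1000_1500",
    "prod_v_500_1000_x_1500_inf", "prod_v_1000_1500_x_1500_inf",
    "prod_a_minf_m5000_x_m5000_0", "prod_a_minf_m5000_x_0_5000",
    "prod_a_minf_m5000_x_5000_inf", "prod_a_m5000_0_x_0_5000",
    "prod_a_m5000_0_x_5000_inf", "prod_a_0_5000_x_5000_inf",
    "N_v_0_500", "N_v_500_1000", "N_v_1000_1500", "N_v_1500_inf",
    "N_a_minf_m5000", "N_a_m5000_0", "N_a_0_5000", "N_a_5000_inf")
}

#' Column dictionary of the descriptor panel
#'
#' @return A data.frame with one row per descriptor: column name, variable
#'   family, units and a short definition. Shipped as
#'   \code{inst/extdata/feature_dictionary.csv} as well.
#' @export
feature_dictionary <- function() {
  path <- system.file("extdata", "feature_dictionary.csv", package = "leukoflow")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compute the 45-descriptor hydrodynamic feature panel of a recording
#'
#' Summaries are computed per leukocyte first -- mean absolute per-frame
#' velocity, mean signed and mean absolute acceleration, rolling-event
#' counts -- and then aggregated over the cell population:
#' \itemize{
#'   \item \code{v_ave}: mean over cells of the mean absolute velocity;
#'     \code{v_med}: median over cells of the same per-cell means.
#'   \item \code{a_ave}: mean over cells of the mean absolute acceleration;
#'     \code{a_med}: median over cells of the mean signed acceleration.
#'   \item Each cell is assigned to exactly one velocity bin (by mean
#'     absolute velocity) and one acceleration bin (by mean signed
#'     acceleration); per-range features are the mean of the per-cell values
#'     within the bin (0 when empty), and the N counts are bin cardinalities.
#'   \item \code{s_vx}, \code{s_ax}: population standard deviations (n-1
#'     denominator) of the per-cell mean velocity and mean signed
#'     acceleration.
#'   \item Ratio, product, and range-interaction features are computed from
#'     the already-aggregated values; interaction products are exactly the
#'     product of their two parent range features.
#' }
#' Undefined ratios (zero denominators, single-cell standard deviations)
#' are returned as \code{NA} and counted in the \code{n_missing} attribute.
#'
#' @param rec A \code{\link{field_recording}}.
#' @param bins A \code{\link{bin_scheme}}.
#' @param epsilon_um_s Dead band for rolling-event counting.
#' @param pooled Use pooled per-frame samples instead of per-leukocyte
#'   means for the global averages and SDs (sensitivity analysis switch;
#'   binning and counts remain per leukocyte).
#' @return A named numeric vector of class \code{hydro_features} with the
#'   45 descriptors in canonical order and attributes \code{n_tracks}
#'   (usable cells) and \code{n_missing}.
#' @export
novel_features <- function(rec, bins = bin_scheme(), epsilon_um_s = 0,
                           pooled = FALSE) {
  stopifnot(inherits(rec, "field_recording"), inherits(bins, "bin_scheme"))
  trs <- usable_tracks(rec)
  n <- length(trs)
  if (n == 0) stop("feature error: no usable tracks (>= 3 points)", call. = FALSE)

  mean_abs_v <- vapply(trs, function(tr) mean(abs(tr$vx)), 0)
  mean_sgn_a <- vapply(trs, function(tr) mean(tr$ax), 0)
  mean_abs_a <- vapply(trs, function(tr) mean(abs(tr$ax)), 0)
  ev <- lapply(trs, rolling_event_counts, epsilon_um_s = epsilon_um_s)
  n_pos <- vapply(ev, `[[`, 0L, "n_pos")
  n_neg <- vapply(ev, `[[`, 0L, "n_neg")

  if (pooled) {
    all_v <- unlist(lapply(trs, function(tr) abs(tr$vx)))
    all_a <- unlist(lapply(trs, function(tr) tr$ax))
    v_ave <- mean(all_v); v_med <- stats::median(all_v)
    a_ave <- mean(abs(all_a)); a_med <- stats::median(all_a)
    s_vx <- if (length(all_v) > 1) stats::sd(all_v) else NA_real_
    s_ax <- if (length(all_a) > 1) stats::sd(all_a) else NA_real_
  } else {
    v_ave <- mean(mean_abs_v)
    v_med <- stats::median(mean_abs_v)
    a_ave <- mean(mean_abs_a)
    a_med <- stats::median(mean_sgn_a)
    s_vx <- if (n > 1) stats::sd(mean_abs_v) else NA_real_
    s_ax <- if (n > 1) stats::sd(mean_sgn_a) else NA_real_
  }

  vbin <- .assign_bin(mean_abs_v, bins$velocity_edges)
  abin <- .assign_bin(mean_sgn_a, bins$acceleration_edges)
  vrange <- vapply(1:4, function(b)
    if (any(vbin == b)) mean(mean_abs_v[vbin == b]) else 0, 0)
  arange <- vapply(1:4, function(b)
    if (any(abin == b)) mean(mean_sgn_a[abin == b]) else 0, 0)
  Nv <- tabulate(vbin, 4L)
  Na <- tabulate(abin, 4L)

  R_pos <- mean(n_pos); R_neg <- mean(n_neg)
  sdiv <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b

  pairs <- utils::combn(4, 2)
  vprod <- vrange[pairs[1, ]] * vrange[pairs[2, ]]
  aprod <- arange[pairs[1, ]] * arange[pairs[2, ]]

  out <- c(
    v_ave, v_med, vrange,
    a_ave, a_med,
    sdiv(v_ave, a_ave), sdiv(v_med, a_med), v_ave * a_ave, v_med * a_med,
    arange,
    R_pos, R_neg, sdiv(R_pos, R_neg),
    s_vx, s_ax, sdiv(s_vx, s_ax), s_vx * s_ax,
    sdiv(v_ave, s_vx), sdiv(a_ave, s_ax),
    vprod, aprod, Nv, Na)
  names(out) <- feature_names()
  structure(out, class = "hydro_features", n_tracks = n,
            n_missing = sum(is.na(out)))
}

#' @export
print.hydro_features <- function(x, ...) {
  cat(sprintf("<hydro_features> %d descriptors from %d cells (%d undefined)\n",
              length(x), attr(x, "n_tracks"), attr(x, "n_missing")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Classical flow-chamber interaction parameters
#'
#' Computes the three standard descriptors of leukocyte-endothelium
#' interaction from a recording:
#' \itemize{
#'   \item \emph{rolling velocity}: the first up to \code{max_cells}
#'     (default 53) tracks crossing a fixed 100-um segment of the flow axis
#'     are timed; each cell contributes \code{segment_um / crossing time}
#'     and the mean is reported.
#'   \item \emph{rolling flux}: the number of distinct cells whose dwell
#'     within a fixed region of interest of area \code{roi_um2} exceeds
#'     \code{min_roll_s} (default 60 s).
#'   \item \emph{adhesion}: cells essentially stationary (net displacement
#'     below \code{stationary_radius_um} over at least \code{min_adhere_s},
#'     default 30 s) are counted in \code{n_fields} randomly placed
#'     sub-fields and the mean count is extrapolated to the 8.77 mm^2 dish
#'     surface.
#' }
#'
#' @param rec A \code{\link{field_recording}}.
#' @param segment_um Length of the timing segment (default 100).
#' @param roi_um2 Area of the rolling-flux region of interest (default 100).
#' @param min_roll_s Minimum dwell for rolling flux, seconds (default 60).
#' @param min_adhere_s Minimum stationary span for adhesion (default 30).
#' @param n_fields Number of random sub-fields for the adhesion count.
#' @param field_frac Linear fraction of the window used as sub-field size
#'   (1 = whole window).
#' @param max_cells Number of consecutive cells timed for rolling velocity.
#' @param stationary_radius_um Displacement radius defining "stationary"
#'   (default 5, about one cell radius).
#' @param dish_area_mm2 Surface the adhesion count is extrapolated to.
#' @param seed Integer seed controlling sub-field placement.
#' @return A list of class \code{classical_params} with
#'   \code{rolling_velocity} (um/s, \code{NA} when no cell crosses the
#'   segment), \code{rolling_flux} (cells) and \code{adhesion}
#'   (extrapolated cells).
#' @export
classical_parameters <- function(rec, segment_um = 100, roi_um2 = 100,
                                 min_roll_s = 60, min_adhere_s = 30,
                                 n_fields = 10, field_frac = 1,
                                 max_cells = 53, stationary_radius_um = 5,
                                 dish_area_mm2 = 8.77, seed = 1L) {
  stopifnot(inherits(rec, "field_recording"))
  wx <- rec$calibration$window_x_um
  wy <- rec$calibration$window_y_um
  if (wx <= 0 || wy <= 0 || field_frac <= 0)
    stop("config error: zero-area field", call. = FALSE)

  # --- rolling velocity over a fixed segment centred in the window
  x0 <- (wx - segment_um) / 2
  x1 <- x0 + segment_um
  crossings <- list()
  for (tr in rec$tracks) {
    i0 <- which(tr$x >= x0)[1]
    i1 <- which(tr$x >= x1)[1]
    if (!is.na(i0) && !is.na(i1) && i1 > i0)
      crossings[[length(crossings) + 1L]] <-
        c(entry = tr$t[i0], dur = tr$t[i1] - tr$t[i0])
  }
  rolling_velocity <- if (length(crossings)) {
    cr <- do.call(rbind, crossings)
    cr <- cr[order(cr[, "entry"]), , drop = FALSE]
    cr <- utils::head(cr, max_cells)
    mean(segment_um / cr[, "dur"])
  } else NA_real_

  # --- rolling flux: dwell of distinct cells in a centred square ROI
  side <- sqrt(roi_um2)
  rx <- c((wx - side) / 2, (wx + side) / 2)
  ry <- c((wy - side) / 2, (wy + side) / 2)
  flux <- 0L
  for (tr in rec$tracks) {
    inside <- tr$x >= rx[1] & tr$x <= rx[2] & tr$y >= ry[1] & tr$y <= ry[2]
    if (!any(inside)) next
    dt_frame <- stats::median(diff(tr$t))
    if (sum(inside) * dt_frame > min_roll_s) flux <- flux + 1L
  }

  # --- adhesion: stationary cells in random sub-fields, extrapolated
  sw <- wx * field_frac; sh <- wy * field_frac
  stationary <- .stationary_positions(rec, min_adhere_s, stationary_radius_um)
  counts <- with_seed(seed, {
    ox <- stats::runif(n_fields, 0, wx - sw)
    oy <- stats::runif(n_fields, 0, wy - sh)
    vapply(seq_len(n_fields), function(f) {
      if (!nrow(stationary)) 0L else
        sum(stationary$x >= ox[f] & stationary$x <= ox[f] + sw &
            stationary$y >= oy[f] & stationary$y <= oy[f] + sh)
    }, 0L)
  })
  field_area_mm2 <- (sw / 1000) * (sh / 1000)
  adhesion <- mean(counts) * dish_area_mm2 / field_area_mm2

  structure(list(rolling_velocity = rolling_velocity,
                 rolling_flux = flux, adhesion = adhesion),
            class = "classical_params")
}

# representative position of every cell with a stationary episode
.stationary_positions <- function(rec, min_adhere_s, radius_um) {
  out <- list()
  for (tr in rec$tracks) {
    n <- length(tr$t)
    if (n < 2) next
    i <- 1L
    while (i <= n) {
      # first sample escaping the stationarity radius around anchor i
      esc <- which((abs(tr$x - tr$x[i]) > radius_um |
                    abs(tr$y - tr$y[i]) > radius_um) & seq_len(n) > i)
      jend <- if (length(esc)) esc[1] - 1L else n
      if (tr$t[jend] - tr$t[i] >= min_adhere_s) {
        out[[length(out) + 1L]] <- data.frame(x = tr$x[i], y = tr$y[i])
        break
      }
      i <- if (length(esc)) esc[1] else n + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(x = numeric(0), y = numeric(0))
}

#' @export
print.classical_params <- function(x, ...) {
  cat(sprintf("<classical_params> rolling velocity %.1f um/s, flux %d cells, adhesion %.1f cells\n",
              x$rolling_velocity, x$rolling_flux, x$adhesion))
  invisible(x)
}
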