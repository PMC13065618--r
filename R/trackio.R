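#' Calibration of a flow-chamber recording
#'
#' Describes the spatial and temporal calibration of the video field: the
#' scale reference used to calibrate pixel distances, the coordinate window
#' (x along the flow direction, y transverse), and the frame interval.
#'
#' @param scale_reference_um Length of the calibration reference, in
#'   micrometres. Defaults to 327.
#' @param window_x_um Extent of the field along the flow axis (default 600).
#' @param window_y_um Transverse extent of the field (default 480).
#' @param frame_interval_s Nominal time between consecutive frames, seconds.
#' @return An object of class \code{calibration_spec}.
#' @export
calibration_spec <- function(scale_reference_um = 327, window_x_um = 600,
                             window_y_um = 480, frame_interval_s = 0.033) {
  vals <- c(scale_reference_um, window_x_um, window_y_um, frame_interval_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all calibration values must be strictly positive", call. = FALSE)
  structure(list(scale_reference_um = scale_reference_um,
                 window_x_um = window_x_um,
                 window_y_um = window_y_um,
                 frame_interval_s = frame_interval_s),
            class = "calibration_spec")
}

#' Single-cell trajectory
#'
#' A track is one leukocyte's ordered samples of time (s) and calibrated
#' position (micrometres); velocity and acceleration series are attached by
#' \code{\link{compute_kinematics}}.
#'
#' @param track_id Opaque label for the cell.
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param x Position along the flow axis, micrometres.
#' @param y Transverse position, micrometres (optional; defaults to 0).
#' @return An object of class \code{lk_track}.
#' @export
lk_track <- function(track_id, t, x, y = rep(0, length(t))) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("track times must be finite and non-negative", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("track times must be strictly increasing", call. = FALSE)
  structure(list(track_id = as.character(track_id), t = t, x = x, y = y,
                 vx = NULL, ax = NULL),
            class = "lk_track")
}

#' Attach finite-difference kinematics to a track
#'
#' Velocity is the forward difference of position over each frame interval,
#' \code{vx[i] = (x[i+1] - x[i]) / (t[i+1] - t[i])}; acceleration is the
#' forward difference of the velocity series indexed to the earlier
#' interval, \code{ax[i] = (vx[i+1] - vx[i]) / (t[i+1] - t[i])}. Irregular
#' sampling is allowed; each difference uses its own time step.
#'
#' @param track An \code{lk_track}.
#' @return The track with \code{vx} (length n-1) and \code{ax} (length n-2)
#'   attached; \code{ax} is \code{numeric(0)} for two-point tracks.
#' @export
compute_kinematics <- function(track) {
  stopifnot(inherits(track, "lk_track"))
  n <- length(track$t)
  if (n < 2) stop("kinematics needs at least 2 points", call. = FALSE)
  dt <- diff(track$t)
  track$vx <- diff(track$x) / dt
  track$ax <- if (n >= 3) diff(track$vx) / dt[seq_len(n - 2)] else numeric(0)
  track
}

#' Flow-chamber field recording
#'
#' All tracks observed in one recorded field, together with its calibration,
#' duration, subject identifier, clinical group and endothelial activation
#' status.
#'
#' @param individual_id Subject label.
#' @param group One of \code{"Healthy"}, \code{"T1D"}, \code{"T2D"}.
#' @param tnf Logical; was the endothelium activated with TNF-alpha?
#' @param duration_s Total recorded span in seconds.
#' @param calibration A \code{\link{calibration_spec}}.
#' @param tracks List of \code{\link{lk_track}} objects.
#' @return An object of class \code{field_recording}.
#' @export
field_recording <- function(individual_id, group = c("Healthy", "T1D", "T2D"),
                            tnf = FALSE, duration_s, calibration = calibration_spec(),
                            tracks = list()) {
  group <- match.arg(group)
  stopifnot(inherits(calibration, "calibration_spec"),
            is.numeric(duration_s), duration_s > 0)
  for (tr in tracks) {
    if (!inherits(tr, "lk_track")) stop("tracks must be lk_track objects", call. = FALSE)
    if (length(tr$t) && (min(tr$t) < 0 || max(tr$t) > duration_s + 1e-9))
      stop("track time range exceeds recording duration", call. = FALSE)
  }
  structure(list(individual_id = as.character(individual_id), group = group,
                 tnf = isTRUE(tnf), duration_s = duration_s,
                 calibration = calibration, tracks = tracks),
            class = "field_recording")
}

#' @export
print.field_recording <- function(x, ...) {
  cat(sprintf("<field_recording> %s [%s%s] %.0f s, %d tracks\n",
              x$individual_id, x$group, if (x$tnf) "+TNF" else "",
              x$duration_s, length(x$tracks)))
  invisible(x)
}

# column-name synonyms accepted in trajectory exports (lower-cased,
# unit suffixes stripped)
.col_synonyms <- list(
  t = c("t", "time", "t_s", "time_s"),
  x = c("x", "x_um", "xpos", "x_position"),
  y = c("y", "y_um", "ypos", "y_position"),
  track_id = c("track_id", "track", "id", "cell", "cell_id")
)

.match_column <- function(nms, key) {
  clean <- tolower(gsub("\\s*\\(.*\\)\\s*$", "", trimws(nms)))
  clean <- gsub("[^a-z0-9]+", "_", clean)
  idx <- which(clean %in% .col_synonyms[[key]])
  if (length(idx)) idx[1] else NA_integer_
}

#' Read a trajectory export file
#'
#' Parses the tab- or comma-separated dialect produced by trajectory
#' software: a header row naming time and position columns (synonyms such
#' as \code{time}, \code{x (um)} are accepted case-insensitively) followed
#' by one row per frame. A file may contain a single track or several
#' distinguished by a \code{track_id} column; alternatively a directory of
#' one-file-per-track exports may be given.
#'
#' Rows with unparseable numbers are skipped and counted; tracks whose time
#' stamps are not strictly increasing are rejected with a warning rather
#' than re-sorted, so that tracking errors are not masked.
#'
#' @param path A file, or a directory of files (one track each).
#' @param calibration A \code{\link{calibration_spec}}.
#' @param individual_id,group,tnf Metadata for the returned recording.
#' @param duration_s Recording span; defaults to the largest observed time.
#' @return A \code{\link{field_recording}} with kinematics computed for all
#'   tracks of at least two points.
#' @export
parse_tracker_export <- function(path, calibration = calibration_spec(),
                                 individual_id = basename(path),
                                 group = "Healthy", tnf = FALSE,
                                 duration_s = NULL) {
  files <- if (dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else if (file.exists(path)) path else
    stop("no such file or directory: ", path, call. = FALSE)
  if (!length(files)) stop("empty recording: no files in ", path, call. = FALSE)

  tracks <- list(); skipped <- 0L; rejected <- 0L
  for (f in files) {
    parsed <- .parse_track_file(f)
    skipped <- skipped + parsed$skipped
    for (tr in parsed$tracks) {
      if (is.null(tr)) rejected <- rejected + 1L else
        tracks[[length(tracks) + 1L]] <- tr
    }
  }
  if (rejected > 0)
    warning(sprintf("%d track(s) rejected (non-monotone time)", rejected),
            call. = FALSE)
  if (skipped > 0)
    message(sprintf("skipped %d malformed row(s)", skipped))
  if (!length(tracks)) stop("empty recording: no usable tracks", call. = FALSE)

  tracks <- lapply(tracks, function(tr)
    if (length(tr$t) >= 2) compute_kinematics(tr) else tr)
  if (is.null(duration_s))
    duration_s <- max(vapply(tracks, function(tr) max(tr$t), 0))
  if (duration_s <= 0) duration_s <- 1
  field_recording(individual_id, group, tnf, duration_s, calibration, tracks)
}

.parse_track_file <- function(f) {
  first <- readLines(f, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first))
    stop("empty recording: ", f, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(f, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "",
                          colClasses = "character", quote = "\"")
  it <- .match_column(names(df), "t")
  ix <- .match_column(names(df), "x")
  iy <- .match_column(names(df), "y")
  iid <- .match_column(names(df), "track_id")
  if (is.na(it)) stop("format error: no time column in ", f, call. = FALSE)
  if (is.na(ix)) stop("format error: no x column in ", f, call. = FALSE)

  tv <- suppressWarnings(as.numeric(df[[it]]))
  xv <- suppressWarnings(as.numeric(df[[ix]]))
  yv <- if (!is.na(iy)) suppressWarnings(as.numeric(df[[iy]])) else rep(0, nrow(df))
  ok <- is.finite(tv) & is.finite(xv) & is.finite(yv)
  skipped <- sum(!ok)
  ids <- if (!is.na(iid)) df[[iid]] else rep(basename(f), nrow(df))

  tracks <- lapply(split(seq_len(nrow(df))[ok], ids[ok]), function(rows) {
    tt <- tv[rows]  # file order within a track; not re-sorted on purpose
    if (any(diff(tt) <= 0)) return(NULL)
    lk_track(ids[rows[1]], tt, xv[rows], yv[rows])
  })
  list(tracks = unname(tracks), skipped = skipped)
}

#' Write a recording in the trajectory-export dialect
#'
#' Emits a single tab-separated file with columns \code{track_id}, \code{t},
#' \code{x}, \code{y}, suitable for re-reading with
#' \code{\link{parse_tracker_export}}. Positions are printed with enough
#' digits for a lossless round trip at micrometre scale.
#'
#' @param rec A \code{\link{field_recording}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracker_export <- function(rec, path) {
  stopifnot(inherits(rec, "field_recording"))
  rows <- lapply(rec$tracks, function(tr)
    data.frame(track_id = tr$track_id, t = tr$t, x = tr$x, y = tr$y))
  df <- do.call(rbind, rows)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("track_id\tt\tx\ty", con)
  writeLines(sprintf("%s\t%.9g\t%.9g\t%.9g", df$track_id, df$t, df$x, df$y), con)
  invisible(path)
}

#' Validate a recording before descriptor extraction
#'
#' Reports, without failing: tracks violating the basic invariants (too few
#' points, non-increasing time), the fraction of samples outside the
#' calibrated window, and whether descriptor extraction is safe (at least
#' one track with three or more points).
#'
#' @param rec A \code{\link{field_recording}}.
#' @return A list of class \code{recording_validation} with elements
#'   \code{n_tracks}, \code{short_tracks}, \code{out_of_window_fraction},
#'   \code{flagged_tracks} and \code{safe_for_descriptors}.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "field_recording"))
  wx <- rec$calibration$window_x_um; wy <- rec$calibration$window_y_um
  n_pts <- 0L; n_out <- 0L
  short <- character(0); flagged <- character(0)
  for (tr in rec$tracks) {
    n <- length(tr$t)
    n_pts <- n_pts + n
    out <- sum(tr$x < 0 | tr$x > wx | tr$y < 0 | tr$y > wy)
    n_out <- n_out + out
    if (out > 0) flagged <- c(flagged, tr$track_id)
    if (n < 3) short <- c(short, tr$track_id)
  }
  usable <- length(rec$tracks) - length(short)
  structure(list(
    n_tracks = length(rec$tracks),
    short_tracks = short,
    flagged_tracks = unique(flagged),
    out_of_window_fraction = if (n_pts > 0) n_out / n_pts else 0,
    safe_for_descriptors = usable >= 1L
  ), class = "recording_validation")
}

#' @export
print.recording_validation <- function(x, ...) {
  cat(sprintf("<recording_validation> %d tracks, %d short, %.1f%% samples out of window, %s\n",
              x$n_tracks, length(x$short_tracks),
              100 * x$out_of_window_fraction,
              if (x$safe_for_descriptors) "safe for descriptors"
              else "UNSAFE for descriptors"))
  invisible(x)
}

# tracks usable for descriptor extraction (>= 3 points, kinematics present)
usable_tracks <- function(rec) {
  Filter(function(tr) length(tr$t) >= 3 && !is.null(tr$vx), rec$tracks)
}
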