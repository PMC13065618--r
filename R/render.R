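#' Render a recording to synthetic frames and re-track it
#'
#' Closes the video loop for validation: each frame of the recording is
#' rendered as Gaussian intensity blobs (one per cell) on a noisy
#' background, cells are re-detected as local intensity maxima above a
#' threshold, and detections are linked frame-to-frame by nearest-neighbour
#' association within a gate distance. The result is a new
#' \code{\link{field_recording}} built purely from the re-tracked
#' detections, so detection and linking errors propagate into it exactly as
#' they would from real video.
#'
#' @param rec A \code{\link{field_recording}} whose tracks are sampled on a
#'   common frame grid (as produced by \code{\link{simulate_recording}}).
#' @param noise_sd Standard deviation of the additive background noise
#'   (blob peak amplitude is 1).
#' @param psf_sigma_um Gaussian blob sigma in micrometres (default 4).
#' @param seed Integer seed for the noise.
#' @param px_um Pixel size of the rendered frames (default 2 um/px).
#' @param gate_um Maximum linking distance between consecutive frames;
#'   defaults to 3 pixels plus the largest plausible free-flow step. A gate
#'   smaller than the largest true per-frame displacement triggers a
#'   warning with the number of broken tracks.
#' @param threshold Detection threshold on blob intensity (default 0.5).
#' @return A re-tracked \code{field_recording}; attribute
#'   \code{n_ambiguities} counts frames where two detections competed for
#'   one track end.
#' @export
render_and_track <- function(rec, noise_sd = 0, psf_sigma_um = 4, seed = 1L,
                             px_um = 2, gate_um = NULL, threshold = 0.5) {
  stopifnot(inherits(rec, "field_recording"))
  dt <- rec$calibration$frame_interval_s
  wx <- rec$calibration$window_x_um
  wy <- rec$calibration$window_y_um
  nx <- ceiling(wx / px_um); ny <- ceiling(wy / px_um)
  times <- seq(0, rec$duration_s, by = dt)

  # positions per frame index (tracks are sampled on the frame grid)
  frame_of <- function(t) as.integer(round(t / dt)) + 1L
  pos <- vector("list", length(times))
  max_step <- 0
  for (tr in rec$tracks) {
    fi <- frame_of(tr$t)
    ok <- fi >= 1 & fi <= length(times)
    if (length(tr$x) > 1) max_step <- max(max_step, max(abs(diff(tr$x))))
    for (k in which(ok)) {
      pos[[fi[k]]] <- rbind(pos[[fi[k]]], c(tr$x[k], tr$y[k]))
    }
  }
  if (is.null(gate_um)) gate_um <- max_step + 3 * px_um
  if (max_step > gate_um)
    warning(sprintf("gate %.1f um below max per-frame displacement %.1f um; tracks may break",
                    gate_um, max_step), call. = FALSE)

  sig_px <- psf_sigma_um / px_um
  half <- max(1L, ceiling(3 * sig_px))
  # pad the canvas so blobs entering at the window edge keep a full
  # neighbourhood and remain detectable
  marg <- half + 1L
  nxp <- nx + 2L * marg; nyp <- ny + 2L * marg
  detections <- with_seed(seed, lapply(seq_along(times), function(f) {
    img <- matrix(if (noise_sd > 0) stats::rnorm(nxp * nyp, 0, noise_sd) else 0,
                  nyp, nxp)
    P <- pos[[f]]
    if (!is.null(P)) for (r in seq_len(nrow(P))) {
      cx <- P[r, 1] / px_um + 0.5 + marg; cy <- P[r, 2] / px_um + 0.5 + marg
      jx <- max(1, floor(cx - half)):min(nxp, ceiling(cx + half))
      jy <- max(1, floor(cy - half)):min(nyp, ceiling(cy + half))
      if (!length(jx) || !length(jy)) next
      gx <- exp(-((jx - cx)^2) / (2 * sig_px^2))
      gy <- exp(-((jy - cy)^2) / (2 * sig_px^2))
      img[jy, jx] <- img[jy, jx] + outer(gy, gx)
    }
    det <- .detect_maxima(img, threshold, px_um)
    det$x <- det$x - marg * px_um
    det$y <- det$y - marg * px_um
    det
  }))

  linked <- .link_detections(detections, times, gate_um)
  tracks <- lapply(seq_along(linked$tracks), function(i) {
    d <- linked$tracks[[i]]
    if (nrow(d) < 2) return(NULL)
    compute_kinematics(lk_track(sprintf("retrack%04d", i), d$t, d$x, d$y))
  })
  tracks <- Filter(Negate(is.null), tracks)
  out <- field_recording(rec$individual_id, rec$group, rec$tnf,
                         rec$duration_s, rec$calibration, tracks)
  attr(out, "n_ambiguities") <- linked$n_ambiguities
  out
}

# local maxima (8-neighbourhood) above threshold, in um coordinates
.detect_maxima <- function(img, threshold, px_um) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3 || nx < 3) return(data.frame(x = numeric(0), y = numeric(0)))
  core <- img[2:(ny - 1), 2:(nx - 1)]
  ismax <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & core >= img[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  idx <- which(ismax, arr.ind = TRUE)
  data.frame(x = (idx[, 2] + 1 - 0.5) * px_um,
             y = (idx[, 1] + 1 - 0.5) * px_um)
}

# greedy nearest-neighbour linking within a gate
.link_detections <- function(detections, times, gate_um) {
  active <- list()   # each: list(rows = data.frame(t,x,y), last = c(x,y))
  done <- list()
  n_amb <- 0L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    used_det <- rep(FALSE, nrow(det))
    if (length(active)) {
      ends <- do.call(rbind, lapply(active, function(a) a$last))
      keep_active <- rep(FALSE, length(active))
      for (a in seq_along(active)) {
        if (!nrow(det)) break
        dists <- sqrt((det$x - ends[a, 1])^2 + (det$y - ends[a, 2])^2)
        dists[used_det] <- Inf
        j <- which.min(dists)
        if (length(j) && is.finite(dists[j]) && dists[j] <= gate_um) {
          if (sum(dists <= gate_um) > 1) n_amb <- n_amb + 1L
          active[[a]]$rows <- rbind(active[[a]]$rows,
                                    data.frame(t = times[f], x = det$x[j], y = det$y[j]))
          active[[a]]$last <- c(det$x[j], det$y[j])
          used_det[j] <- TRUE
          keep_active[a] <- TRUE
        }
      }
      done <- c(done, lapply(active[!keep_active], `[[`, "rows"))
      active <- active[keep_active]
    }
    if (any(!used_det)) {
      for (j in which(!used_det)) {
        active[[length(active) + 1L]] <- list(
          rows = data.frame(t = times[f], x = det$x[j], y = det$y[j]),
          last = c(det$x[j], det$y[j]))
      }
    }
  }
  done <- c(done, lapply(active, `[[`, "rows"))
  list(tracks = done, n_ambiguities = n_amb)
}
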