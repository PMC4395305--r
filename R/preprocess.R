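#' Zero-phase band-pass filter for node time series
#'
#' Applies a second-order Butterworth band-pass (default 0.009-0.08 Hz, the
#' standard resting-state connectivity band) identically to every node's
#' series, run forward and backward (`signal::filtfilt`) so no phase lag
#' distorts subsequent correlations. Each series is demeaned before filtering,
#' so the DC component is always removed; with `low_hz = 0` a low-pass is used
#' instead of a band-pass.
#'
#' @param ts a [timeseries_matrix()].
#' @param low_hz,high_hz band edges in Hz; requires
#'   `0 <= low_hz < high_hz < 1/(2*tr)` (Nyquist).
#' @return A filtered [timeseries_matrix()] of the same shape.
#' @export
#' @examples
#' ts <- generate_modular_timeseries(
#'   modular_series_spec(4, 2, 0.5, 0.1, n_frames = 240, tr = 2, seed = 1))
#' filt <- bandpass_filter(ts)
bandpass_filter <- function(ts, low_hz = 0.009, high_hz = 0.08) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  nyquist <- 1 / (2 * ts$tr)
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("band edges must satisfy 0 <= low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyquist))
  }
  bf <- if (low_hz == 0) {
    signal::butter(2, high_hz / nyquist, type = "low")
  } else {
    signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  }
  filt_one <- function(x) signal::filtfilt(bf, x - mean(x))
  out <- t(apply(ts$values, 1, filt_one))
  timeseries_matrix(out, tr = ts$tr, frame_ids = ts$frame_ids)
}

#' Regress nuisance signals out of node time series
#'
#' Projects every node's series onto the orthogonal complement of the column
#' space of `regressors` (an intercept is always included), leaving residuals
#' whose inner product with every regressor is zero to numerical precision.
#' A rank-deficient regressor matrix is handled by the pivoted QR least-norm
#' solution with a warning.
#'
#' @param ts a [timeseries_matrix()].
#' @param regressors numeric frame x p matrix (or data frame) of nuisance
#'   signals, e.g. motion parameters and mean tissue signals.
#' @return A [timeseries_matrix()] of residual series.
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  X <- as.matrix(regressors)
  if (nrow(X) != n_frames(ts)) {
    stop("'regressors' must have one row per frame")
  }
  if (ncol(X) < 1L) stop("at least one nuisance regressor is required")
  Xi <- cbind(1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    warning("nuisance regressor matrix is rank deficient; ",
            "using the least-norm projection")
  }
  resid <- qr.resid(qx, t(ts$values))
  timeseries_matrix(t(resid), tr = ts$tr, frame_ids = ts$frame_ids)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum(|delta translations|) + radius * sum(|delta rotations|)` for
#' each transition `t = 2..T`: the summed absolute frame-to-frame change of
#' the three translations (mm) plus the three rotations (radians) converted to
#' arc length on a sphere of `rotation_radius` mm (50 mm by convention,
#' roughly the mean cortical distance from the head centre).
#'
#' @param motion data frame or matrix with 6 columns: 3 translations in mm
#'   followed by 3 rotations in radians, one row per frame.
#' @param rotation_radius sphere radius in mm used to convert rotations to
#'   displacements.
#' @return Numeric vector of length `n_frames - 1`; element `t-1` is the FD of
#'   the transition into frame `t`.
#' @export
#' @examples
#' m <- generate_motion_trace(20, spike_frames = 10, spike_fd = 0.8, seed = 1)
#' compute_fd(m)[9]   # 0.8
compute_fd <- function(motion, rotation_radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) stop("'motion' must have 6 columns (3 translations mm, 3 rotations rad)")
  if (nrow(m) < 2L) stop("at least 2 frames are required")
  if (anyNA(m) || any(!is.finite(m))) stop("motion parameters must be finite")
  d <- abs(diff(m))
  unname(rowSums(d[, 1:3, drop = FALSE]) +
           rotation_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS: RMS frame-to-frame signal change, as percent of mean signal
#'
#' `DVARS_t` is the root mean square over nodes of the signal change from
#' frame `t-1` to frame `t`, divided by the grand mean signal and expressed in
#' percent. Band-passed, nuisance-regressed data are near zero-mean, so the
#' normalising mean should then be taken from the raw data and passed as
#' `baseline_mean`.
#'
#' @param ts a [timeseries_matrix()].
#' @param baseline_mean grand mean signal used as the 100% reference; defaults
#'   to `mean(ts$values)`.
#' @return Numeric vector of length `n_frames - 1`, in percent.
#' @export
compute_dvars <- function(ts, baseline_mean = NULL) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  if (n_frames(ts) < 2L) stop("at least 2 frames are required")
  m <- if (is.null(baseline_mean)) mean(ts$values) else baseline_mean
  if (!is.finite(m) || abs(m) < sqrt(.Machine$double.eps)) {
    stop("grand mean signal is (near) zero; supply 'baseline_mean' from the raw data")
  }
  d <- diff(t(ts$values))                # transitions x nodes
  unname(sqrt(rowMeans(d^2)) / abs(m) * 100)
}

#' Motion scrubbing by FD and DVARS thresholds
#'
#' Removes every frame that terminates a transition whose framewise
#' displacement exceeds `fd_thresh` OR whose DVARS exceeds `dvars_thresh`
#' (default 0.5 mm and 0.5%). Only transitions between frames that were
#' adjacent in the original acquisition (consecutive `frame_ids`) are scored,
#' so scrubbing already-scrubbed data removes nothing. Optionally the removal
#' mask is extended `extend_before`/`extend_after` frames around each
#' offender (default 0).
#'
#' @param ts a [timeseries_matrix()] (typically filtered and regressed).
#' @param motion 6-column motion table aligned with the frames of `ts`.
#' @param fd_thresh FD threshold in mm (> 0).
#' @param dvars_thresh DVARS threshold in percent (> 0).
#' @param rotation_radius passed to [compute_fd()].
#' @param extend_before,extend_after number of neighbouring frames to remove
#'   around each offending frame.
#' @param baseline_mean passed to [compute_dvars()].
#' @return A list with elements `ts` (surviving frames, original `frame_ids`
#'   preserved), `motion` (matching rows) and `report`, a `scrub_report` list
#'   with `fd`, `dvars`, `removed_frames` (original frame ids) and
#'   `n_removed`.
#' @export
#' @examples
#' ts <- generate_modular_timeseries(
#'   modular_series_spec(6, 2, 0.4, 0.1, n_frames = 80, tr = 2, seed = 2))
#' m <- generate_motion_trace(80, spike_frames = c(10, 50), spike_fd = 1, seed = 2)
#' scrub(ts, m)$report$removed_frames
scrub <- function(ts, motion, fd_thresh = 0.5, dvars_thresh = 0.5,
                  rotation_radius = 50, extend_before = 0, extend_after = 0,
                  baseline_mean = NULL) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  if (fd_thresh <= 0 || dvars_thresh <= 0) stop("scrub thresholds must be > 0")
  if (nrow(as.matrix(motion)) != n_frames(ts)) {
    stop("'motion' must have one row per frame of 'ts'")
  }
  fd <- compute_fd(motion, rotation_radius)
  dvars <- compute_dvars(ts, baseline_mean)
  contiguous <- diff(ts$frame_ids) == 1L
  offending <- which((fd > fd_thresh | dvars > dvars_thresh) & contiguous) + 1L
  bad <- unique(unlist(lapply(offending, function(i) {
    (i - extend_before):(i + extend_after)
  })))
  bad <- sort(bad[bad >= 1L & bad <= n_frames(ts)])
  keep <- setdiff(seq_len(n_frames(ts)), bad)
  if (length(keep) < 3L) {
    stop("fewer than 3 frames survive the scrub thresholds; ",
         "subject is unusable")
  }
  report <- structure(
    list(fd = fd, dvars = dvars,
         removed_frames = ts$frame_ids[bad], n_removed = length(bad)),
    class = "scrub_report")
  list(ts = timeseries_matrix(ts$values[, keep, drop = FALSE], tr = ts$tr,
                              frame_ids = ts$frame_ids[keep]),
       motion = as.data.frame(as.matrix(motion)[keep, , drop = FALSE]),
       report = report)
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("scrub_report: %d frame(s) removed", x$n_removed))
  if (x$n_removed > 0) {
    cat(": ", paste(x$removed_frames, collapse = ", "), sep = "")
  }
  cat(sprintf("\n  max FD = %.3f mm, max DVARS = %.3f%%\n",
              max(x$fd), max(x$dvars)))
  invisible(x)
}

#' Serialize a scrub report to JSON
#'
#' @param report a `scrub_report` as returned by [scrub()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scrub_report <- function(report, path) {
  jsonlite::write_json(
    list(fd = report$fd, dvars = report$dvars,
         removed_frames = report$removed_frames,
         n_removed = report$n_removed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
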