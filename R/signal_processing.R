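# Signal containers and preprocessing: zero-phase Butterworth filtering,
# impact-onset detection, and cutting the synchronized analysis window.

#' Uniformly sampled axial force trace
#'
#' @param force numeric vector of axial force samples, N (compressive
#'   positive).
#' @param fs sampling rate, Hz (default 1e6, the load-cell acquisition rate).
#' @param channel `"cranial"` or `"caudal"`.
#' @return object of class `force_trace` with fields `force`, `fs`,
#'   `channel`; sample i is at time (i-1)/fs.
#' @export
force_trace <- function(force, fs = 1e6, channel = c("cranial", "caudal")) {
  channel <- match.arg(channel)
  force <- as.numeric(force)
  stopifnot_finite(force, "force trace")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(force = force, fs = fs, channel = channel),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace (%s): %d samples at %g Hz (%.2f ms), range [%.1f, %.1f] N\n",
              x$channel, length(x$force), x$fs,
              1000 * (length(x$force) - 1) / x$fs,
              min(x$force), max(x$force)))
  invisible(x)
}

trace_times <- function(trace) (seq_along(trace$force) - 1) / trace$fs

#' Marker trajectory block
#'
#' @param data array of dim `n_frames x 3 x n_markers` (m), coordinate order
#'   x, y, z, marker names in the third dimnames.
#' @param fs sampling rate, Hz (default 4000); may be `NA` when `times` is
#'   given explicitly.
#' @param times optional explicit frame times, s.
#' @return object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(data, fs = 4000, times = NULL) {
  if (length(dim(data)) != 3L || dim(data)[2] != 3L) {
    stop("data must be an n_frames x 3 x n_markers array")
  }
  if (is.null(dimnames(data)[[3]])) stop("markers must be named")
  if (anyNA(data)) stop("marker trajectories contain missing samples")
  if (is.null(times)) times <- (seq_len(dim(data)[1]) - 1) / fs
  if (length(times) != dim(data)[1]) stop("times/frame mismatch")
  structure(list(data = data, fs = fs, times = as.numeric(times)),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("Marker trajectories: %d markers x %d frames%s\n",
              dim(x$data)[3], dim(x$data)[1],
              if (is.finite(x$fs)) sprintf(" at %g Hz", x$fs) else ""))
  invisible(x)
}

marker_names <- function(traj) dimnames(traj$data)[[3]]

#' Zero-lag low-pass Butterworth filter
#'
#' One forward and one backward pass of a Butterworth low-pass filter, with
#' odd-reflective padding of 3 x `order` samples at both ends to suppress
#' edge transients. With `design = "net"` each pass uses a filter of order
#' `order`/2 so the net attenuation order equals `order` (the common
#' biomechanics reading of an n-th order zero-lag filter); `"per_pass"`
#' designs each pass at the full `order`.
#'
#' @param x numeric signal (or a [force_trace()], returned filtered).
#' @param fs sampling rate, Hz (taken from the trace if one is given).
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order net filter order; even.
#' @param design `"net"` or `"per_pass"`.
#' @return filtered signal of the same type as `x`.
#' @export
zero_lag_lowpass <- function(x, fs = NULL, cutoff, order = 4,
                             design = c("net", "per_pass")) {
  design <- match.arg(design)
  if (inherits(x, "force_trace")) {
    out <- x
    out$force <- zero_lag_lowpass(x$force, x$fs, cutoff, order, design)
    return(out)
  }
  if (is.null(fs)) stop("fs is required for plain numeric signals")
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even integer")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and Nyquist")
  }
  # pad with at least 3x the filter order and enough samples to cover the
  # impulse-response tail (~fs/cutoff) so the two pass orders commute at the
  # edges
  pad <- max(3L * as.integer(order), 3L * as.integer(ceiling(fs / cutoff)))
  n <- length(x)
  pad <- min(pad, n - 2L)
  if (n <= 3L * order + 1) stop("signal too short for edge padding")
  bf <- signal::butter(if (design == "net") order / 2 else order,
                       cutoff / (fs / 2), type = "low")
  # odd reflection about the end samples preserves level and slope; each
  # pass starts from the steady state of its leading sample so a constant
  # signal passes exactly (unit DC gain)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  np <- max(length(bf$a), length(bf$b)) - 1
  run <- function(s) {
    signal::filter(bf$b, bf$a, s, init.x = rep(s[1], np),
                   init.y = rep(s[1], np))
  }
  yp <- rev(run(rev(run(xp))))
  as.numeric(yp[(pad + 1):(pad + n)])
}

#' Detect the impact onset on a force trace
#'
#' The onset is the first sample whose force, measured above the preload
#' baseline, strictly exceeds the threshold. The baseline is the median of
#' the pre-impact portion of the trace (first `baseline_s`, capped at half
#' the recording), which makes the 200 N criterion robust to the 152 N
#' preload sitting just below it.
#'
#' @param trace a [force_trace()] (filter first).
#' @param threshold_N onset threshold above baseline, N (default 200).
#' @param baseline_s length of the baseline window, s (default 0.010).
#' @return list with `index` (1-based sample), `time` (s) and `baseline` (N).
#' @export
detect_impact_onset <- function(trace, threshold_N = 200, baseline_s = 0.010) {
  f <- trace$force
  n_base <- max(1L, min(round(baseline_s * trace$fs), floor(length(f) / 2)))
  baseline <- median(f[seq_len(n_base)])
  idx <- which(f - baseline > threshold_N)
  if (length(idx) == 0) stop("no impact detected: threshold never exceeded")
  list(index = idx[1], time = (idx[1] - 1) / trace$fs, baseline = baseline)
}

#' Cut the synchronized analysis window from force and marker recordings
#'
#' Returns the force samples in `[onset, onset + window_s]` (baseline
#' subtracted by default, so the window holds the net external load the
#' simulator applies on top of the model's internal preload) and every marker
#' frame whose timestamp falls in the same closed interval. Times in the
#' returned objects are relative to the onset.
#'
#' @param force a [force_trace()].
#' @param markers a [marker_trajectories()] sharing the force time base.
#' @param onset result of [detect_impact_onset()] or an onset time in s.
#' @param window_s analysis window, s (default 0.005).
#' @param subtract_baseline subtract the onset baseline from the force window.
#' @return list with `force` (force_trace), `markers`
#'   (marker_trajectories), `onset_time` and `baseline`.
#' @export
align_and_window <- function(force, markers, onset, window_s = 0.005,
                             subtract_baseline = TRUE) {
  if (is.list(onset)) {
    onset_time <- onset$time
    baseline <- onset$baseline %||% 0
  } else {
    onset_time <- onset
    baseline <- 0
  }
  tf <- trace_times(force)
  t_end <- onset_time + window_s
  if (t_end > tf[length(tf)] + 1e-12) {
    stop("window extends past the end of the force recording")
  }
  if (t_end > markers$times[length(markers$times)] + 1e-12) {
    stop("window extends past the end of the marker recording")
  }
  keep_f <- tf >= onset_time - 1e-12 & tf <= t_end + 1e-12
  fwin <- force$force[keep_f]
  if (subtract_baseline) fwin <- fwin - baseline
  keep_m <- markers$times >= onset_time - 1e-12 &
    markers$times <= t_end + 1e-12
  mwin <- marker_trajectories(
    markers$data[keep_m, , , drop = FALSE],
    fs = markers$fs,
    times = markers$times[keep_m] - onset_time
  )
  list(force = force_trace(fwin, fs = force$fs, channel = force$channel),
       markers = mwin, onset_time = onset_time, baseline = baseline)
}
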