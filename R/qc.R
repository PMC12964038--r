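#' Framewise displacement from rigid-body motion parameters
#'
#' The standard scalar head-motion summary: for each frame, the sum of
#' absolute backward differences of the three translations (mm) plus the
#' three rotations (rad) converted to arc length on a sphere of
#' \code{head_radius}. The first frame has FD = 0.
#'
#' @param motion frame-by-6 matrix or data frame: translations x, y, z in mm
#'   then rotations in rad.
#' @param head_radius rotation-to-mm conversion radius in mm (default 50).
#' @return numeric vector of FD per frame (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("framewise_displacement: expected 6 motion columns, got ",
         ncol(motion))
  }
  stopifnot(nrow(motion) >= 2, all(is.finite(motion)))
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion-based subject exclusion rule
#'
#' A run is excluded when either (a) the mean FD exceeds
#' \code{mean_thresh} mm, or (b) the proportion of frames with FD above
#' \code{large_thresh} mm exceeds \code{prop_thresh}. Both comparisons are
#' strict, so a run sitting exactly on a threshold is retained.
#'
#' @param fd_series FD per frame in mm.
#' @param mean_thresh mean-FD threshold (mm).
#' @param prop_thresh allowed proportion of large FDs.
#' @param large_thresh definition of a "large" FD (mm).
#' @return list of class \code{qc_report}: \code{fd_series}, \code{mean_fd},
#'   \code{prop_large}, \code{excluded}, \code{reason} ("mean",
#'   "proportion", or "").
#' @export
qc_exclude <- function(fd_series, mean_thresh = 0.30, prop_thresh = 0.20,
                       large_thresh = 0.30) {
  stopifnot(length(fd_series) > 0, all(is.finite(fd_series)))
  mean_fd <- mean(fd_series)
  prop_large <- mean(fd_series > large_thresh)
  excl_mean <- mean_fd > mean_thresh
  excl_prop <- prop_large > prop_thresh
  structure(
    list(fd_series = fd_series, mean_fd = mean_fd, prop_large = prop_large,
         excluded = excl_mean || excl_prop,
         reason = if (excl_mean) "mean" else if (excl_prop) "proportion"
                  else ""),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: mean FD %.3f mm, %.1f%% large FDs -> %s\n", x$mean_fd,
              100 * x$prop_large,
              if (x$excluded) paste0("EXCLUDED (", x$reason, ")")
              else "included"))
  invisible(x)
}

#' Zero-phase band-pass filter for PPG traces
#'
#' Butterworth filtering applied forward and backward
#' (\code{signal::filtfilt}), passing the cardiac band and removing baseline
#' drift and scanner interference. The band-pass is realized as a cascade of
#' a 2nd-order high-pass and a 4th-order low-pass: a single band-pass design
#' is numerically ill-conditioned when the band is this narrow relative to
#' the sampling rate.
#'
#' @param x numeric PPG trace.
#' @param fs sampling rate in Hz (must exceed twice the upper edge).
#' @param low,high band edges in Hz.
#' @return filtered trace of the same length.
#' @export
bandpass_ppg <- function(x, fs, low = 0.05, high = 3) {
  if (fs <= 2 * high) {
    stop("bandpass_ppg: sampling rate ", fs, " Hz too low for a ", high,
         " Hz band edge")
  }
  x <- as.numeric(x)
  x <- x - mean(x)
  # mirror-pad to absorb the filter's edge transients
  n_pad <- min(length(x) - 1, round(10 * fs))
  xp <- c(rev(x[seq_len(n_pad)]), x, rev(x[length(x) - seq_len(n_pad) + 1]))
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  yp <- signal::filtfilt(lp, signal::filtfilt(hp, xp))
  as.numeric(yp[n_pad + seq_along(x)])
}

#' Detect systolic peaks in a filtered PPG trace
#'
#' Local-maximum detection with an adaptive amplitude threshold (a fraction
#' of the median per-second block maximum) and a refractory period that
#' suppresses dicrotic-notch double counts.
#'
#' @param x filtered PPG trace.
#' @param fs sampling rate in Hz.
#' @param refractory minimum inter-beat interval in seconds.
#' @param rel_threshold amplitude threshold as a fraction of the typical
#'   beat amplitude.
#' @return numeric vector of beat times in seconds (strictly increasing).
#' @export
detect_beats <- function(x, fs, refractory = 0.25, rel_threshold = 0.5) {
  n <- length(x)
  stopifnot(n / fs >= 10)
  # typical beat amplitude: median of per-second block maxima
  block <- floor((seq_len(n) - 1) / fs)
  block_max <- tapply(x, block, max)
  thr <- rel_threshold * stats::median(block_max)
  is_peak <- c(FALSE, diff(sign(diff(x))) < 0, FALSE) & x > thr
  cand <- which(is_peak)
  if (length(cand) == 0) stop("detect_beats: no beats found")
  # enforce refractory period, keeping the larger peak of any close pair
  min_gap <- refractory * fs
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  (keep - 1) / fs
}

#' Mean heart rate from beat times
#'
#' Defined through the mean inter-beat interval: \code{60 / mean(diff(
#' beat_times))}. A companion definition, beat count over elapsed time, is
#' returned as an attribute; the two differ under missed beats.
#'
#' @param beat_times beat times in seconds (>= 2 beats).
#' @return mean heart rate in bpm, with attributes \code{n_beats} and
#'   \code{hr_count} (count-based rate).
#' @export
mean_hr <- function(beat_times) {
  if (length(beat_times) < 2) stop("mean_hr: need at least 2 beats")
  stopifnot(all(diff(beat_times) > 0))
  ibi <- diff(beat_times)
  hr <- 60 / mean(ibi)
  structure(hr, n_beats = length(beat_times),
            hr_count = 60 * (length(beat_times) - 1) /
              (max(beat_times) - min(beat_times)))
}

#' PPG trace to mean heart rate
#'
#' Convenience wrapper: band-pass filter, beat detection, mean HR.
#'
#' @param x raw PPG trace.
#' @param fs sampling rate in Hz.
#' @param ... passed to [detect_beats()].
#' @return list of class \code{hr_result}: \code{beat_times},
#'   \code{mean_hr}, \code{n_beats}, \code{quality_flags} (fraction of
#'   implausible inter-beat intervals).
#' @export
ppg_to_hr <- function(x, fs, ...) {
  filt <- bandpass_ppg(x, fs)
  beats <- detect_beats(filt, fs, ...)
  hr <- mean_hr(beats)
  ibi <- diff(beats)
  structure(
    list(beat_times = beats, mean_hr = as.numeric(hr),
         n_beats = length(beats),
         quality_flags = list(
           prop_irregular_ibi = mean(abs(ibi / stats::median(ibi) - 1) > 0.5)
         )),
    class = "hr_result"
  )
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("Mean HR %.2f bpm from %d beats (%.1f%% irregular IBIs)\n",
              x$mean_hr, x$n_beats,
              100 * x$quality_flags$prop_irregular_ibi))
  invisible(x)
}
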