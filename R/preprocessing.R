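#' FIR band-pass filter with group-delay compensation
#'
#' Applies a linear-phase windowed-sinc (Hamming) band-pass filter to one
#' audio channel. The default analysis band is 250 Hz--10 kHz: the low edge
#' rejects muscle sound and motion artifact, the high edge removes
#' high-frequency artifact while keeping the kHz-range components of joint
#' acoustic emissions. The filter order is `4 * fs / low` rounded to even and
#' the constant group delay is compensated (with edge reflection padding) so
#' the output is time-aligned with the input and has the same length.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; requires `0 < low < high < fs/2`.
#' @return filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' fs <- 25000
#' t <- seq(0, 0.2, by = 1 / fs)
#' x <- sin(2 * pi * 1000 * t)
#' y <- bandpass(x, fs, 250, 10000)
bandpass <- function(x, fs, low = 250, high = 10000) {
  check_scalar_number(fs, "fs", min = 0, strict_min = TRUE)
  check_scalar_number(low, "low", min = 0, strict_min = TRUE)
  if (high >= fs / 2) {
    stop_invalid(sprintf(
      "upper band edge (%g Hz) is at or above the Nyquist frequency (%g Hz)", high, fs / 2
    ))
  }
  if (low >= high) stop_invalid("`low` must be below `high`")
  if (!is.numeric(x) || anyNA(x)) stop_invalid("`x` must be a numeric vector with finite samples")
  ord <- 2L * as.integer(ceiling(2 * fs / low))   # 4*fs/low rounded up to even
  ord <- min(ord, 2L * ((length(x) - 1L) %/% 2L))
  if (ord < 8L) stop_invalid("signal too short for the band-pass filter order")
  b <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  gd <- ord %/% 2L
  # reflect-pad so the startup/teardown transients fall on mirrored samples
  pad_l <- rev(x[seq_len(gd) + 1L])
  pad_r <- rev(x[length(x) - seq_len(gd)])
  y <- signal::fftfilt(b, c(pad_l, x, pad_r))
  out <- y[(2L * gd + 1L):(2L * gd + length(x))]
  attributes(out) <- attributes(x)[c("fs", "cycle_starts")]
  if (is.null(attr(out, "fs"))) attr(out, "fs") <- fs
  out
}

# clamp a requested analysis band to what a given sampling rate supports;
# used by config/pipeline paths at desk-scale rates
effective_band <- function(fs, band) {
  if (band[2] >= fs / 2) {
    clamped <- 0.45 * fs
    warn(sprintf(
      "upper band edge %g Hz is not representable at fs = %g Hz; clamped to %g Hz",
      band[2], fs, clamped
    ), class = "jae_band_clamped")
    band[2] <- clamped
  }
  band
}

find_local_minima <- function(a) {
  n <- length(a)
  cand <- integer(0)
  if (n >= 2 && a[1] < a[2]) cand <- 1L
  if (n >= 3) {
    i <- 2:(n - 1)
    cand <- c(cand, i[a[i] < a[i - 1] & a[i] <= a[i + 1]])
  }
  cand
}

find_local_maxima <- function(a) {
  n <- length(a)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[a[i] > a[i - 1] & a[i] >= a[i + 1]]
}

# 5 Hz low-pass of the motion angle, reflect-padded, delay-compensated
smooth_angle <- function(angle, fs, cutoff = 5) {
  ord <- 2L * as.integer(ceiling(fs / cutoff))
  ord <- min(ord, 2L * ((length(angle) - 1L) %/% 4L))
  if (ord < 4L) return(angle)
  b <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
  gd <- ord %/% 2L
  pad_l <- rev(angle[seq_len(gd) + 1L])
  pad_r <- rev(angle[length(angle) - seq_len(gd)])
  y <- signal::fftfilt(b, c(pad_l, angle, pad_r))
  y[(2L * gd + 1L):(2L * gd + length(angle))]
}

#' Segment an audio recording into flexion/extension cycles
#'
#' Cycle boundaries are taken from the synchronized motion trace: the knee
#' angle is low-pass filtered (5 Hz) and its local minima -- full flexion,
#' the start of each cycle -- are detected with a minimum separation of half
#' the median cycle period (ties broken by the earliest index). Boundaries
#' are then mapped to audio sample indices. As a quality-control cross-check
#' the audio envelope (block-averaged absolute signal at the motion rate,
#' 5 Hz low-passed) is correlated with the angle trace and the correlation is
#' attached to the result; the motion minima remain the sole source of the
#' boundaries.
#'
#' @param x audio sample vector.
#' @param motion a `jae_motion` trace covering the same session.
#' @param fs_audio audio sampling rate (Hz); defaults to `attr(x, "fs")`.
#' @param lowpass_cutoff motion smoothing cutoff in Hz.
#' @return tibble with columns `cycle`, `start`, `end` (1-based, half-open
#'   `[start, end)` audio sample indices) and attribute `qc_correlation`.
#' @export
segment_cycles <- function(x, motion, fs_audio = attr(x, "fs"), lowpass_cutoff = 5) {
  stopifnot(inherits(motion, "jae_motion"))
  if (is.null(fs_audio)) stop_invalid("`fs_audio` is required when `x` carries no fs attribute")
  fs_motion <- attr(motion, "fs")
  n_audio <- length(x)
  dur_gap <- abs(n_audio / fs_audio - nrow(motion) / fs_motion)
  if (dur_gap > 1 / fs_motion + 1e-9) {
    abort(sprintf(
      "audio (%.3f s) and motion (%.3f s) durations differ by more than one motion sample",
      n_audio / fs_audio, nrow(motion) / fs_motion
    ), class = "jae_invalid_input")
  }

  a <- smooth_angle(motion$angle_deg, fs_motion, lowpass_cutoff)
  # a genuine extension peak must rise and fall by a good fraction of the
  # range of motion on both sides; filter-edge ripples do not
  rng <- diff(range(a))
  prominent <- vapply(find_local_maxima(a), function(i) {
    left <- min(a[seq_len(i)])
    right <- min(a[i:length(a)])
    (a[i] - max(left, right)) >= 0.25 * rng
  }, logical(1))
  if (rng <= 0 || !any(prominent)) {
    abort("no flexion/extension cycle found: motion trace has no interior extension peak",
          class = "jae_segmentation_failure")
  }
  mins <- find_local_minima(a)
  if (length(mins) > 2L) {
    med <- median(diff(mins))
    keep <- mins[1]
    for (m in mins[-1]) if (m - keep[length(keep)] >= 0.5 * med) keep <- c(keep, m)
    mins <- keep
  }
  if (length(mins) < 1L) {
    abort("no flexion/extension cycle found in motion trace", class = "jae_segmentation_failure")
  }

  starts <- as.integer(round((mins - 1) * fs_audio / fs_motion)) + 1L
  starts <- starts[starts <= n_audio]
  ends <- c(starts[-1], n_audio + 1L)
  keep <- ends > starts
  starts <- starts[keep]
  ends <- ends[keep]
  # a trailing fragment much shorter than a cycle is the end boundary of the
  # final cycle, not a cycle of its own
  if (length(starts) > 1L) {
    lens <- ends - starts
    if (lens[length(lens)] < 0.5 * median(lens[-length(lens)])) {
      ends <- ends[-length(ends)]
      starts <- starts[-length(starts)]
      ends[length(ends)] <- n_audio + 1L
    }
  }
  out <- tibble::tibble(cycle = seq_along(starts), start = starts, end = ends)

  # QC: low-rate audio envelope vs angle trace
  r <- fs_audio / fs_motion
  nb <- min(nrow(motion), floor(n_audio / r))
  env <- vapply(seq_len(nb), function(i) {
    lo <- as.integer(floor((i - 1) * r)) + 1L
    hi <- min(n_audio, as.integer(floor(i * r)))
    mean(abs(x[lo:hi]))
  }, numeric(1))
  env_s <- smooth_angle(env, fs_motion, lowpass_cutoff)
  qc <- suppressWarnings(stats::cor(env_s, a[seq_len(nb)]))
  attr(out, "qc_correlation") <- if (is.na(qc)) 0 else qc
  out
}

#' Split a cycle of audio into fixed-length frames
#'
#' Partitions a cycle's samples into non-overlapping contiguous frames of
#' `round(frame_len * fs)` samples; the trailing remainder shorter than one
#' frame is discarded. At the protocol's 4 s cycle period and 400 ms frames
#' this yields 10 frames per cycle.
#'
#' @param x sample vector for one cycle.
#' @param frame_len frame length in seconds.
#' @param fs sampling rate in Hz.
#' @return numeric matrix, one frame per row.
#' @export
frame_cycle <- function(x, frame_len = 0.4, fs = attr(x, "fs")) {
  if (is.null(fs)) stop_invalid("`fs` is required")
  len <- as.integer(round(frame_len * fs))
  if (len < 8L) stop_invalid("`frame_len * fs` must be at least 8 samples")
  if (length(x) < len) {
    abort(sprintf("cycle of %d samples is shorter than one %d-sample frame", length(x), len),
          class = "jae_too_short_cycle")
  }
  nf <- length(x) %/% len
  matrix(x[seq_len(nf * len)], nrow = nf, byrow = TRUE)
}
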