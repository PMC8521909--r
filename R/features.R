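#' Feature registry
#'
#' Fixes the set, definitions and column order of the per-frame base features
#' and the per-cycle summary statistics. The default registry holds the ten
#' canonical short-time audio features -- four time-domain (zero-crossing
#' rate, energy, RMS amplitude, signal entropy) and six spectral (centroid,
#' spread, roll-off, entropy, flux, mean power spectral density) -- each
#' summarized across a cycle's frames by mean, population SD and coefficient
#' of variation, giving 30 columns. The registry is the extension point for
#' larger feature sets (the study this models used 49 descriptors per cycle;
#' its exact list is not public, so the default is an explicit stand-in and
#' every downstream stage is dimension-agnostic).
#'
#' Frame conventions: spectral features are computed from the one-sided
#' magnitude spectrum of the Hann-windowed frame; time-domain features use
#' the raw frame. Spectral flux of a cycle's first frame is 0 by convention;
#' an all-zero frame yields 0 for every spectral feature rather than NaN.
#'
#' @param extra_cycle_features named list of functions `f(samples, fs)`
#'   returning one number per cycle, appended after the summary columns.
#' @return a `jae_registry` object.
#' @export
jae_registry <- function(extra_cycle_features = list()) {
  base <- list(
    zcr = function(ctx) {
      s <- sign(ctx$frame)
      s <- s[s != 0]
      sum(s[-1] != s[-length(s)]) / (length(ctx$frame) / ctx$fs)
    },
    energy = function(ctx) sum(ctx$frame^2),
    rms = function(ctx) sqrt(mean(ctx$frame^2)),
    signal_entropy = function(ctx) {
      nsub <- 32L
      len <- length(ctx$frame) %/% nsub
      if (len < 1L) return(0)
      e <- colSums(matrix(ctx$frame[seq_len(nsub * len)]^2, nrow = len))
      tot <- sum(e)
      if (tot <= 0) return(0)
      p <- e / tot
      p <- p[p > 0]
      -sum(p * log2(p))
    },
    spectral_centroid = function(ctx) {
      if (ctx$power_total <= 0) return(0)
      sum(ctx$freqs * ctx$power) / ctx$power_total
    },
    spectral_spread = function(ctx) {
      if (ctx$power_total <= 0) return(0)
      mu <- sum(ctx$freqs * ctx$power) / ctx$power_total
      sqrt(sum((ctx$freqs - mu)^2 * ctx$power) / ctx$power_total)
    },
    spectral_rolloff = function(ctx) {
      if (ctx$power_total <= 0) return(0)
      ctx$freqs[which(cumsum(ctx$power) >= 0.85 * ctx$power_total)[1]]
    },
    spectral_entropy = function(ctx) {
      if (ctx$power_total <= 0) return(0)
      p <- ctx$power / ctx$power_total
      p <- p[p > 0]
      -sum(p * log2(p))
    },
    spectral_flux = function(ctx) {
      if (is.null(ctx$prev_mag_norm)) return(0)
      sum((ctx$mag_norm - ctx$prev_mag_norm)^2)
    },
    spectral_density = function(ctx) mean(ctx$psd)
  )
  structure(
    list(base_features = base,
         statistics = c("mean", "sd", "cov"),
         extra_cycle_features = extra_cycle_features),
    class = "jae_registry"
  )
}

#' @export
print.jae_registry <- function(x, ...) {
  cat("<jae_registry>", length(x$base_features), "base features x",
      length(x$statistics), "statistics +", length(x$extra_cycle_features),
      "cycle features =", registry_ncol(x), "columns\n")
  invisible(x)
}

registry_columns <- function(registry) {
  cols <- as.vector(t(outer(names(registry$base_features), registry$statistics, paste, sep = "_")))
  c(cols, names(registry$extra_cycle_features))
}

registry_ncol <- function(registry) {
  length(registry$base_features) * length(registry$statistics) +
    length(registry$extra_cycle_features)
}

# per-frame analysis context shared by all base feature functions
frame_context <- function(frame, fs, prev_mag_norm = NULL) {
  n <- length(frame)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))   # Hann
  spec <- fft(frame * w)
  half <- seq_len(n %/% 2 + 1L)
  mag <- Mod(spec)[half]
  power <- mag^2
  mag_tot <- sum(mag)
  list(
    frame = frame, fs = fs,
    freqs = (half - 1) * fs / n,
    mag = mag, power = power, power_total = sum(power),
    mag_norm = if (mag_tot > 0) mag / mag_tot else mag,
    prev_mag_norm = prev_mag_norm,
    psd = power / (fs * sum(w^2))
  )
}

#' Compute base features for one frame
#'
#' @param frame numeric sample vector (length >= 8).
#' @param fs sampling rate in Hz.
#' @param registry a [jae_registry()].
#' @param prev the previous frame's context (internal; governs spectral
#'   flux), or `NULL` for a cycle's first frame.
#' @return named numeric vector, one value per base feature.
#' @export
#' @examples
#' fs <- 8000
#' frame <- sin(2 * pi * 1000 * (0:3199) / fs)
#' round(frame_features(frame, fs)[["spectral_centroid"]])
frame_features <- function(frame, fs, registry = jae_registry(), prev = NULL) {
  if (length(frame) < 8L) stop_invalid("frame must have at least 8 samples")
  if (anyNA(frame) || any(!is.finite(frame))) stop_invalid("frame must be finite")
  ctx <- frame_context(frame, fs, prev_mag_norm = prev)
  vapply(registry$base_features, function(f) f(ctx), numeric(1))
}

#' Summarize per-frame features into one cycle row
#'
#' For every base feature the mean, population SD (n denominator) and
#' coefficient of variation (SD / (|mean| + 1e-12)) are computed across the
#' cycle's frames; any extra cycle features from the registry are appended.
#'
#' @param frame_mat numeric matrix of per-frame base features (frames in
#'   rows, base features in columns, as produced by [frame_features()]).
#' @param registry a [jae_registry()].
#' @param samples,fs the cycle's raw samples and rate, only needed when the
#'   registry defines extra cycle features.
#' @return named numeric vector of length `registry_ncol(registry)`.
#' @export
cycle_features <- function(frame_mat, registry = jae_registry(),
                           samples = NULL, fs = NULL) {
  if (is.null(dim(frame_mat))) frame_mat <- matrix(frame_mat, nrow = 1)
  if (nrow(frame_mat) < 1L) stop_invalid("at least one frame is required")
  eps <- 1e-12
  out <- unlist(lapply(seq_len(ncol(frame_mat)), function(j) {
    v <- frame_mat[, j]
    m <- mean(v)
    s <- sd_pop(v)
    c(m, s, s / (abs(m) + eps))
  }), use.names = FALSE)
  extra <- vapply(registry$extra_cycle_features, function(f) f(samples, fs), numeric(1))
  setNames(c(out, extra), registry_columns(registry))
}

# filtered channel -> per-cycle feature rows
channel_feature_rows <- function(x, motion, fs, band, frame_len, registry) {
  segs <- segment_cycles(x, motion, fs_audio = fs)
  purrr::map(seq_len(nrow(segs)), function(k) {
    slice <- x[segs$start[k]:(segs$end[k] - 1L)]
    frames <- frame_cycle(as.numeric(slice), frame_len, fs)
    prev <- NULL
    fmat <- matrix(0, nrow(frames), length(registry$base_features))
    for (i in seq_len(nrow(frames))) {
      ctx <- frame_context(frames[i, ], fs, prev_mag_norm = prev)
      fmat[i, ] <- vapply(registry$base_features, function(f) f(ctx), numeric(1))
      prev <- ctx$mag_norm
    }
    cycle_features(fmat, registry, samples = slice, fs = fs)
  })
}

#' Build the feature matrix X for a cohort
#'
#' Runs the full per-session chain -- band-pass filtering, motion-based cycle
#' segmentation, 400 ms framing, per-frame feature extraction and per-cycle
#' summarization -- over every (subject, channel, cycle) and assembles the
#' row matrix X. Each row is one movement cycle from one accelerometer;
#' metadata columns (`subject_id`, `visit`, `channel`, `cycle`, `label`)
#' precede the feature columns, whose order is fixed by the registry. Labels
#' are 0 for healthy, 1 for arthritic, `NA` for follow-up sessions (unknown
#' ground truth). If the requested band is not representable at the cohort's
#' sampling rate the upper edge is clamped to `0.45 * fs` with a warning.
#'
#' @param cohort a `jae_cohort` tibble (or any tibble with the same columns).
#' @param band two-element band-pass edges in Hz.
#' @param frame_len frame length in seconds.
#' @param registry a [jae_registry()].
#' @return a tibble (feature matrix) with one row per subject x channel x
#'   cycle.
#' @export
build_feature_matrix <- function(cohort, band = c(250, 10000), frame_len = 0.4,
                                 registry = jae_registry()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  fs <- cohort$fs_audio[1]
  band <- effective_band(fs, band)
  label_of <- c(healthy = 0, jia = 1)

  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    ses <- cohort[i, ]
    motion <- ses$motion[[1]]
    feats <- purrr::imap(ses$audio[[1]], function(x, ch) {
      y <- bandpass(as.numeric(x), fs, band[1], band[2])
      rws <- withCallingHandlers(
        channel_feature_rows(y, motion, fs, band, frame_len, registry),
        jae_segmentation_failure = function(e) {
          abort(sprintf("session %s/%s channel %s: %s",
                        ses$subject_id, ses$visit, ch, conditionMessage(e)),
                class = "jae_segmentation_failure")
        }
      )
      if (length(rws) == 0) {
        abort(sprintf("session %s/%s channel %s yielded zero cycles",
                      ses$subject_id, ses$visit, ch),
              class = "jae_segmentation_failure")
      }
      tibble::tibble(
        subject_id = ses$subject_id, visit = ses$visit, channel = ch,
        cycle = seq_along(rws),
        label = unname(label_of[ses$group_label])[1],
        !!!as.data.frame(do.call(rbind, rws))
      )
    })
    dplyr::bind_rows(feats)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "registry_columns") <- registry_columns(registry)
  out
}

#' Fit / apply column standardization
#'
#' `standardize_fit()` computes per-column means and SDs of a training
#' feature matrix; `standardize_apply()` centers and scales any matrix with
#' those statistics. During cross-validation the statistics are always fit on
#' the training fold only, so held-out subjects never leak into the scaling.
#' Zero-variance columns have their SD replaced by a tiny epsilon (with a
#' warning), which maps a constant column to all zeros.
#'
#' @param x a feature matrix tibble (metadata columns are ignored).
#' @return `standardize_fit()`: a `jae_standardization` object with `mean`
#'   and `sd` vectors; `standardize_apply()`: the transformed tibble.
#' @export
standardize_fit <- function(x) {
  cols <- feature_columns(x)
  if (nrow(x) < 2L) stop_invalid("at least 2 rows are required to fit standardization")
  m <- vapply(x[cols], mean, numeric(1))
  s <- vapply(x[cols], stats::sd, numeric(1))
  zero <- !is.finite(s) | s <= 0
  if (any(zero)) {
    warn(sprintf("%d zero-variance column(s) guarded with epsilon SD: %s",
                 sum(zero), paste(head(cols[zero], 5), collapse = ", ")),
         class = "jae_zero_variance")
    s[zero] <- 1e-12
  }
  structure(list(mean = m, sd = s, columns = cols), class = "jae_standardization")
}

#' @rdname standardize_fit
#' @param stats a `jae_standardization` from `standardize_fit()`.
#' @export
standardize_apply <- function(stats, x) {
  stopifnot(inherits(stats, "jae_standardization"))
  if (!all(stats$columns %in% names(x))) {
    stop_invalid("feature matrix is missing columns present at standardization fit time")
  }
  for (j in stats$columns) {
    x[[j]] <- (x[[j]] - stats$mean[[j]]) / stats$sd[[j]]
  }
  x
}
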