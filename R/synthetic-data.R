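#' Acoustic class profile for synthetic joint sounds
#'
#' Describes how one class of knee sounds is synthesized. Healthy knees
#' articulate smoothly and their acoustic emissions are noise-like; inflamed
#' joints add periodic high-energy transient clicks in every
#' flexion/extension cycle. A profile fixes the background noise level and
#' the click process (rate per cycle, amplitude relative to the noise floor,
#' carrier frequency range and exponential decay constant).
#'
#' @param label `"healthy"` or `"jia"` (juvenile idiopathic arthritis).
#' @param noise_rms RMS of the Gaussian background noise (acceleration a.u.).
#' @param clicks_per_cycle mean number of clicks per movement cycle
#'   (Poisson rate; 0 gives pure noise). Defaults: 0 for healthy, 6 for jia.
#' @param click_amplitude peak click amplitude as a multiple of `noise_rms`.
#'   Defaults: 0 for healthy, 10 for jia.
#' @param click_freq_range two-element Hz vector; each click's sinusoidal
#'   carrier frequency is drawn uniformly from this range.
#' @param click_decay exponential envelope time constant in seconds.
#' @return a `jae_profile` list.
#' @export
#' @examples
#' class_profile("healthy")
#' class_profile("jia", click_amplitude = 12)
class_profile <- function(label = c("healthy", "jia"),
                          noise_rms = 1,
                          clicks_per_cycle = NULL,
                          click_amplitude = NULL,
                          click_freq_range = c(2000, 8000),
                          click_decay = 0.003) {
  label <- match.arg(label)
  clicks_per_cycle <- clicks_per_cycle %||% if (label == "jia") 6 else 0
  click_amplitude <- click_amplitude %||% if (label == "jia") 10 else 0
  check_scalar_number(noise_rms, "noise_rms", min = 0, strict_min = TRUE)
  check_scalar_number(clicks_per_cycle, "clicks_per_cycle", min = 0)
  check_scalar_number(click_amplitude, "click_amplitude", min = 0)
  check_scalar_number(click_decay, "click_decay", min = 0, strict_min = TRUE)
  if (length(click_freq_range) != 2L || any(!is.finite(click_freq_range)) ||
      click_freq_range[1] <= 0 || click_freq_range[2] < click_freq_range[1]) {
    stop_invalid("`click_freq_range` must be an increasing pair of positive frequencies (Hz)")
  }
  structure(
    list(
      label = label, noise_rms = noise_rms,
      clicks_per_cycle = clicks_per_cycle, click_amplitude = click_amplitude,
      click_freq_range = as.numeric(click_freq_range), click_decay = click_decay
    ),
    class = "jae_profile"
  )
}

# follow-up default: same class of signal with the click process attenuated,
# emulating a large reduction in click amplitude and frequency after treatment
attenuate_profile <- function(profile, factor = 5) {
  profile$clicks_per_cycle <- profile$clicks_per_cycle / factor
  profile$click_amplitude <- profile$click_amplitude / factor
  profile
}

#' Specification of a synthetic cohort
#'
#' Fixes every condition of a synthetic study: group sizes, follow-up count,
#' movement protocol (cycles per recording, cycle period), sampling rates,
#' channel count and the per-class acoustic profiles. The default mirrors the
#' study design the package models: 25 arthritic and 18 healthy subjects,
#' 10 arthritic subjects re-recorded at follow-up, 10 flexion/extension
#' cycles at one cycle every 4 s, four accelerometer channels per subject
#' (two per knee) and a 50 Hz motion trace. The default audio rate is a
#' desk-scale 25 kHz: the analysis band tops out at 10 kHz so a 25 kHz rate
#' preserves it while keeping a full cohort in memory.
#'
#' @param n_jia,n_healthy baseline group sizes.
#' @param n_followup number of arthritic subjects with a follow-up session
#'   (`<= n_jia`).
#' @param cycles_per_recording flexion/extension cycles per session.
#' @param cycle_period nominal seconds per cycle.
#' @param fs_audio,fs_motion sampling rates (Hz) of the accelerometers and
#'   the ankle inertial measurement unit.
#' @param channels_per_subject accelerometer channels per subject (1--4 use
#'   the canonical knee positions).
#' @param profiles named list with elements `healthy` and `jia`, each a
#'   [class_profile()].
#' @param followup_profile profile for follow-up sessions; default is the
#'   `jia` profile with clicks attenuated 5-fold.
#' @param period_jitter,amplitude_jitter relative SD of per-cycle period and
#'   range-of-motion variation (0 = metronomic movement).
#' @param seed master integer seed; per-subject streams are derived with
#'   [jae_seed()].
#' @return a `jae_cohort_spec` list.
#' @export
cohort_spec <- function(n_jia = 25, n_healthy = 18, n_followup = 10,
                        cycles_per_recording = 10, cycle_period = 4,
                        fs_audio = 25000, fs_motion = 50,
                        channels_per_subject = 4,
                        profiles = list(healthy = class_profile("healthy"),
                                        jia = class_profile("jia")),
                        followup_profile = NULL,
                        period_jitter = 0.03, amplitude_jitter = 0.05,
                        seed = 1L) {
  check_scalar_number(n_jia, "n_jia", min = 0)
  check_scalar_number(n_healthy, "n_healthy", min = 0)
  check_scalar_number(n_followup, "n_followup", min = 0)
  if (n_followup > n_jia) stop_invalid("`n_followup` must not exceed `n_jia`")
  check_scalar_number(cycles_per_recording, "cycles_per_recording", min = 1)
  check_scalar_number(cycle_period, "cycle_period", min = 0, strict_min = TRUE)
  check_scalar_number(fs_audio, "fs_audio", min = 0, strict_min = TRUE)
  check_scalar_number(fs_motion, "fs_motion", min = 0, strict_min = TRUE)
  check_scalar_number(channels_per_subject, "channels_per_subject", min = 1)
  stopifnot(is.list(profiles), all(c("healthy", "jia") %in% names(profiles)))
  for (p in profiles) {
    if (!inherits(p, "jae_profile")) stop_invalid("`profiles` entries must be class_profile() objects")
    if (p$click_freq_range[2] >= fs_audio / 2) {
      stop_invalid(sprintf(
        "profile '%s' click_freq_range upper bound (%g Hz) must be below the audio Nyquist frequency (%g Hz)",
        p$label, p$click_freq_range[2], fs_audio / 2
      ))
    }
  }
  followup_profile <- followup_profile %||% attenuate_profile(profiles$jia, 5)
  structure(
    list(
      n_jia = as.integer(n_jia), n_healthy = as.integer(n_healthy),
      n_followup = as.integer(n_followup),
      cycles_per_recording = as.integer(cycles_per_recording),
      cycle_period = cycle_period, fs_audio = fs_audio, fs_motion = fs_motion,
      channels_per_subject = as.integer(channels_per_subject),
      profiles = profiles, followup_profile = followup_profile,
      period_jitter = period_jitter, amplitude_jitter = amplitude_jitter,
      seed = as.integer(seed)
    ),
    class = "jae_cohort_spec"
  )
}

channel_names <- function(k) {
  base <- c("left_medial", "left_lateral", "right_medial", "right_lateral")
  if (k <= 4) base[seq_len(k)] else c(base, paste0("ch", 5:k))
}

#' Generate a knee-angle motion trace
#'
#' Simulates the ankle-worn inertial measurement unit trace of a seated
#' subject performing unloaded knee flexion/extension: the knee angle swings
#' smoothly from flexion (90 deg) to full extension and back once per cycle.
#' Per-cycle period and range of motion get small seeded jitter. The sample
#' index at which each cycle begins is returned as ground truth for testing
#' segmentation.
#'
#' @param n_cycles number of full flexion/extension cycles (`>= 1`).
#' @param cycle_period nominal seconds per cycle.
#' @param fs_motion motion sampling rate in Hz; must exceed `2 / cycle_period`.
#' @param seed integer seed.
#' @param period_jitter,amplitude_jitter relative SD of per-cycle jitter.
#' @return a `jae_motion` tibble with columns `time_s`, `angle_deg` and
#'   attributes `fs` (Hz) and `cycle_starts` (1-based sample indices).
#' @export
#' @examples
#' m <- generate_motion_trace(10, 4, 50, seed = 1)
#' nrow(m)                    # 2000 samples = 40 s at 50 Hz
#' attr(m, "cycle_starts")
generate_motion_trace <- function(n_cycles, cycle_period, fs_motion, seed = 1L,
                                  period_jitter = 0, amplitude_jitter = 0) {
  check_scalar_number(n_cycles, "n_cycles", min = 1)
  check_scalar_number(cycle_period, "cycle_period", min = 0, strict_min = TRUE)
  check_scalar_number(fs_motion, "fs_motion", min = 0, strict_min = TRUE)
  if (fs_motion <= 2 / cycle_period) {
    stop_invalid("`fs_motion` must exceed 2 / cycle_period to resolve the movement")
  }
  n_cycles <- as.integer(n_cycles)
  with_seed(seed, {
    pj <- pmax(pmin(rnorm(n_cycles, 0, period_jitter), 0.3), -0.3)
    aj <- pmax(pmin(rnorm(n_cycles, 0, amplitude_jitter), 0.3), -0.3)
  })
  periods <- cycle_period * (1 + pj)
  n_per <- pmax(2L, as.integer(round(periods * fs_motion)))
  starts <- cumsum(c(1L, n_per[-n_cycles]))
  angle <- unlist(lapply(seq_len(n_cycles), function(k) {
    t_local <- seq_len(n_per[k]) - 1
    range_deg <- 90 * (1 + aj[k])
    90 + range_deg / 2 * (1 - cos(2 * pi * t_local / n_per[k]))
  }), use.names = FALSE)
  n <- length(angle)
  out <- tibble::tibble(time_s = (seq_len(n) - 1) / fs_motion, angle_deg = angle)
  structure(out,
            fs = fs_motion, cycle_starts = as.integer(starts),
            class = c("jae_motion", class(out)))
}

#' Generate one channel of synthetic joint audio
#'
#' Builds an audio-rate accelerometer signal spanning the motion trace:
#' Gaussian background noise at the profile's RMS plus, in every movement
#' cycle, a Poisson number of transient clicks. Each click is an
#' exponentially decaying sinusoid with seeded onset phase, carrier frequency
#' and oscillator phase.
#'
#' @param profile a [class_profile()].
#' @param motion a `jae_motion` trace (defines duration and cycle boundaries).
#' @param fs_audio audio sampling rate (Hz); must exceed twice the profile's
#'   upper click frequency.
#' @param seed integer seed.
#' @return numeric vector of samples with attribute `fs`.
#' @export
generate_audio <- function(profile, motion, fs_audio, seed = 1L) {
  stopifnot(inherits(profile, "jae_profile"), inherits(motion, "jae_motion"))
  check_scalar_number(fs_audio, "fs_audio", min = 0, strict_min = TRUE)
  if (profile$click_freq_range[2] >= fs_audio / 2) {
    stop_invalid(sprintf(
      "click_freq_range upper bound (%g Hz) is at or above the Nyquist frequency (%g Hz)",
      profile$click_freq_range[2], fs_audio / 2
    ))
  }
  fs_motion <- attr(motion, "fs")
  duration <- nrow(motion) / fs_motion
  n <- as.integer(round(duration * fs_audio))
  starts_a <- as.integer(round((attr(motion, "cycle_starts") - 1) * fs_audio / fs_motion)) + 1L
  ends_a <- c(starts_a[-1] - 1L, n)

  with_seed(seed, {
    x <- rnorm(n, 0, profile$noise_rms)
    if (profile$click_amplitude > 0 || profile$clicks_per_cycle > 0) {
      amp <- profile$click_amplitude * profile$noise_rms
      tau <- profile$click_decay
      len <- max(8L, as.integer(round(6 * tau * fs_audio)))
      t_click <- (seq_len(len) - 1) / fs_audio
      env <- exp(-t_click / tau)
      for (k in seq_along(starts_a)) {
        n_clicks <- rpois(1, profile$clicks_per_cycle)
        if (n_clicks == 0) next
        hi <- ends_a[k] - len + 1L
        if (hi <= starts_a[k]) next
        for (j in seq_len(n_clicks)) {
          pos <- as.integer(floor(runif(1, starts_a[k], hi + 1)))
          f <- runif(1, profile$click_freq_range[1], profile$click_freq_range[2])
          phase <- runif(1, 0, 2 * pi)
          idx <- pos:(pos + len - 1L)
          x[idx] <- x[idx] + amp * env * sin(2 * pi * f * t_click + phase)
        }
      }
    }
  })
  structure(x, fs = fs_audio, cycle_starts = starts_a)
}

#' Generate a full synthetic cohort of recording sessions
#'
#' Produces one session per baseline subject (arthritic and healthy) plus
#' follow-up sessions for the first `n_followup` arthritic subjects. Every
#' session carries one motion trace shared by all of its audio channels, the
#' ground-truth cycle boundaries, and a group label; follow-up sessions are
#' labelled `"unknown"` because their disease status is not a training-grade
#' ground truth. Per-subject/channel seeds are derived by hashing
#' `(spec$seed, subject_id, visit, channel)`, so waveforms are bit-reproducible
#' and independent of cohort composition.
#'
#' @param spec a [cohort_spec()].
#' @return a `jae_cohort` tibble with one row per session and list-columns
#'   `audio` (named list of channel sample vectors), `motion` (the
#'   `jae_motion` trace) and `cycle_starts` (ground-truth audio sample
#'   indices).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_jia = 2, n_healthy = 2, n_followup = 1,
#'   cycles_per_recording = 2, fs_audio = 4000, channels_per_subject = 2,
#'   profiles = list(healthy = class_profile("healthy", click_freq_range = c(500, 1500)),
#'                   jia = class_profile("jia", click_freq_range = c(500, 1500)))))
#' coh[, c("subject_id", "visit", "group_label")]
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "jae_cohort_spec"))
  chans <- channel_names(spec$channels_per_subject)
  subjects <- tibble::tibble(
    subject_id = c(sprintf("jia%02d", seq_len(spec$n_jia)),
                   sprintf("hc%02d", seq_len(spec$n_healthy))),
    group = c(rep("jia", spec$n_jia), rep("healthy", spec$n_healthy)),
    visit = "baseline"
  )
  followups <- tibble::tibble(
    subject_id = sprintf("jia%02d", seq_len(spec$n_followup)),
    group = "followup",
    visit = "followup"
  )
  plan <- dplyr::bind_rows(subjects, followups)

  rows <- purrr::pmap(plan, function(subject_id, group, visit) {
    profile <- switch(group,
      healthy = spec$profiles$healthy,
      jia = spec$profiles$jia,
      followup = spec$followup_profile
    )
    motion <- generate_motion_trace(
      spec$cycles_per_recording, spec$cycle_period, spec$fs_motion,
      seed = jae_seed(spec$seed, subject_id, visit, "motion"),
      period_jitter = spec$period_jitter, amplitude_jitter = spec$amplitude_jitter
    )
    audio <- lapply(setNames(chans, chans), function(ch) {
      generate_audio(profile, motion, spec$fs_audio,
                     seed = jae_seed(spec$seed, subject_id, visit, ch))
    })
    starts <- attr(audio[[1]], "cycle_starts")
    tibble::tibble(
      subject_id = subject_id, visit = visit,
      group_label = if (visit == "followup") "unknown" else group,
      fs_audio = spec$fs_audio, fs_motion = spec$fs_motion,
      audio = list(audio), motion = list(motion),
      cycle_starts = list(starts)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("jae_cohort", class(out))
  attr(out, "spec") <- spec
  out
}
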