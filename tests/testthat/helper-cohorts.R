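# Shared synthetic study conditions and a per-process cache so expensive
# cohorts/feature matrices are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# reduced-rate profiles for cheap unit tests: clicks moved into the band
# that a 4 kHz recording can represent
fast_profiles <- function(amplitude = 12, clicks = 6) {
  list(
    healthy = class_profile("healthy", click_freq_range = c(500, 1500)),
    jia = class_profile("jia", clicks_per_cycle = clicks,
                        click_amplitude = amplitude,
                        click_freq_range = c(500, 1500))
  )
}

fast_spec <- function(n_jia = 4, n_healthy = 4, n_followup = 0, seed = 1,
                      cycles = 5, channels = 2, amplitude = 12, clicks = 6,
                      fs_audio = 4000, followup_profile = NULL) {
  cohort_spec(
    n_jia = n_jia, n_healthy = n_healthy, n_followup = n_followup,
    cycles_per_recording = cycles, cycle_period = 4,
    fs_audio = fs_audio, fs_motion = 50, channels_per_subject = channels,
    profiles = fast_profiles(amplitude, clicks),
    followup_profile = followup_profile, seed = seed
  )
}

fast_features <- function(spec) {
  build_feature_matrix(generate_cohort(spec), band = c(250, 1800))
}

# full-rate strong-effect cohort (study-scale sampling, strong clicks):
# 16 subjects, four channels, ten 4 s cycles at 25 kHz
strong_features <- function() {
  cached("strong16", {
    prof <- list(healthy = class_profile("healthy"),
                 jia = class_profile("jia", click_amplitude = 12))
    spec <- cohort_spec(n_jia = 8, n_healthy = 8, n_followup = 0,
                        profiles = prof, seed = 20260923)
    build_feature_matrix(generate_cohort(spec))
  })
}

# small feature matrix for structural/model tests
small_features <- function() {
  cached("small8", fast_features(fast_spec(seed = 42)))
}

# synthetic pre-standardized feature-matrix tibble with one planted
# informative column among noise columns
planted_matrix <- function(n_subjects = 10, rows_per_subject = 8, p_noise = 8,
                           signal_col = "sig", effect = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_subjects * rows_per_subject
  label <- rep(rep(c(0, 1), length.out = n_subjects), each = rows_per_subject)
  vals <- matrix(rnorm(n * p_noise), n, p_noise,
                 dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  sig <- effect * (label - 0.5) + rnorm(n)
  out <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", seq_len(n_subjects)), each = rows_per_subject),
    visit = "baseline",
    channel = "ch1",
    cycle = rep(seq_len(rows_per_subject), n_subjects),
    label = label
  )
  out[[signal_col]] <- sig
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  standardize_apply(standardize_fit(out), out)
}
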