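#' Pipeline configuration
#'
#' Bundles and validates every tunable of the end-to-end analysis. Defaults
#' are the protocol constants of the study design the package models: a
#' 250 Hz--10 kHz analysis band, 5 Hz motion low-pass, 400 ms frames, 4 s
#' movement cycles, a 0.5 decision threshold -- with audio at a desk-scale
#' 25 kHz (the band tops out at 10 kHz, so 25 kHz preserves it). If the
#' upper band edge is not representable at the configured rate it is clamped
#' to `0.45 * fs_audio` with a warning, so reduced-rate configurations stay
#' valid end to end.
#'
#' @param fs_audio,fs_motion sampling rates (Hz).
#' @param band band-pass edges (Hz).
#' @param lowpass_cutoff motion-smoothing cutoff (Hz) for segmentation.
#' @param frame_len frame length (s).
#' @param cycle_period nominal movement cycle period (s).
#' @param threshold decision threshold on probabilities.
#' @param ridge logistic ridge penalty.
#' @param perm_cap cycle-subset cap per heatmap cell.
#' @param max_features top-feature sweep depth for the heatmap.
#' @param seed master seed.
#' @param n_jia,n_healthy,n_followup,cycles_per_recording,channels_per_subject
#'   cohort design, see [cohort_spec()].
#' @param profiles,followup_profile acoustic class profiles, see
#'   [cohort_spec()].
#' @return a validated `jae_config` list.
#' @export
jae_config <- function(fs_audio = 25000, fs_motion = 50,
                       band = c(250, 10000), lowpass_cutoff = 5,
                       frame_len = 0.4, cycle_period = 4,
                       threshold = 0.5, ridge = 1e-4,
                       perm_cap = 1000, max_features = 20, seed = 1L,
                       n_jia = 25, n_healthy = 18, n_followup = 10,
                       cycles_per_recording = 10, channels_per_subject = 4,
                       profiles = NULL, followup_profile = NULL) {
  check_scalar_number(fs_audio, "fs_audio", min = 0, strict_min = TRUE)
  check_scalar_number(fs_motion, "fs_motion", min = 0, strict_min = TRUE)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop_invalid("`band` must be an increasing pair of positive frequencies")
  }
  band <- effective_band(fs_audio, band)
  check_scalar_number(lowpass_cutoff, "lowpass_cutoff", min = 0, strict_min = TRUE)
  check_scalar_number(frame_len, "frame_len", min = 0, strict_min = TRUE)
  if (round(frame_len * fs_audio) < 8) stop_invalid("`frame_len * fs_audio` must be >= 8 samples")
  check_scalar_number(threshold, "threshold", min = 0)
  if (threshold >= 1) stop_invalid("`threshold` must be in [0, 1)")
  check_scalar_number(ridge, "ridge", min = 0)
  check_scalar_number(perm_cap, "perm_cap", min = 1)
  check_scalar_number(max_features, "max_features", min = 1)

  profiles <- profiles %||% list(healthy = class_profile("healthy"),
                                 jia = class_profile("jia"))
  spec <- cohort_spec(
    n_jia = n_jia, n_healthy = n_healthy, n_followup = n_followup,
    cycles_per_recording = cycles_per_recording, cycle_period = cycle_period,
    fs_audio = fs_audio, fs_motion = fs_motion,
    channels_per_subject = channels_per_subject,
    profiles = profiles, followup_profile = followup_profile, seed = seed
  )
  structure(
    list(fs_audio = fs_audio, fs_motion = fs_motion, band = band,
         lowpass_cutoff = lowpass_cutoff, frame_len = frame_len,
         cycle_period = cycle_period, threshold = threshold, ridge = ridge,
         perm_cap = as.integer(perm_cap), max_features = as.integer(max_features),
         seed = as.integer(seed), cohort = spec),
    class = "jae_config"
  )
}

config_as_list <- function(config) {
  spec <- config$cohort
  list(
    fs_audio = config$fs_audio, fs_motion = config$fs_motion,
    band = config$band, lowpass_cutoff = config$lowpass_cutoff,
    frame_len = config$frame_len, cycle_period = config$cycle_period,
    threshold = config$threshold, ridge = config$ridge,
    perm_cap = config$perm_cap, max_features = config$max_features,
    seed = config$seed,
    cohort = list(
      n_jia = spec$n_jia, n_healthy = spec$n_healthy,
      n_followup = spec$n_followup,
      cycles_per_recording = spec$cycles_per_recording,
      channels_per_subject = spec$channels_per_subject,
      profiles = lapply(spec$profiles, unclass),
      followup_profile = unclass(spec$followup_profile)
    )
  )
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline end to end
#'
#' Simulate, (optionally) export audio, extract features, evaluate with
#' leave-one-subject-out cross-validation, rank features, sweep the
#' feature-by-cycle accuracy grid, and score the longitudinal pairs. Every
#' stage's output is written under `out_dir`; a `manifest.json` records the
#' configuration, package version and the MD5 checksum of each artifact, so
#' two runs with the same configuration can be verified byte-identical.
#'
#' @param config a [jae_config()].
#' @param out_dir output directory.
#' @param write_audio also export per-channel WAV files and motion CSVs
#'   (off by default; the waveforms can be large and are regenerable from
#'   the seed).
#' @return a list with the in-memory stage results (`cohort`, `features`,
#'   `loso`, `ranking`, `heatmap`, `paired`, `ttest`) plus `out_dir`,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_audio = FALSE) {
  stopifnot(inherits(config, "jae_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config$cohort)
  if (write_audio) write_cohort(cohort, file.path(out_dir, "sessions"))

  features <- build_feature_matrix(cohort, band = config$band,
                                   frame_len = config$frame_len)
  readr::write_csv(features, file.path(out_dir, "features.csv"), progress = FALSE)

  loso <- loso_evaluate(features, ridge = config$ridge, threshold = config$threshold)
  readr::write_csv(loso$predictions, file.path(out_dir, "cycle_predictions.csv"),
                   progress = FALSE)
  readr::write_csv(loso$subjects, file.path(out_dir, "subject_scores.csv"),
                   progress = FALSE)
  readr::write_csv(loso$metrics$roc, file.path(out_dir, "roc.csv"), progress = FALSE)
  write_report_json(
    c(glance(loso), list(config = config_as_list(config))),
    file.path(out_dir, "report.json")
  )

  base_std <- standardize_apply(
    standardize_fit(dplyr::filter(features, .data$visit == "baseline")),
    dplyr::filter(features, .data$visit == "baseline")
  )
  ranking <- rank_features(base_std, ridge = config$ridge)
  readr::write_csv(ranking, file.path(out_dir, "ranking.csv"), progress = FALSE)

  heatmap <- accuracy_heatmap(
    features, ranking,
    max_features = min(config$max_features, nrow(ranking)),
    perm_cap = config$perm_cap, ridge = config$ridge,
    threshold = config$threshold, seed = config$seed
  )
  readr::write_csv(heatmap$grid, file.path(out_dir, "heatmap.csv"), progress = FALSE)

  paired <- NULL
  ttest <- NULL
  if (config$cohort$n_followup >= 2) {
    paired <- score_pairs(features, ridge = config$ridge)
    ttest <- paired_one_tailed_ttest(paired)
    write_report_json(
      list(pairs = paired, t_test = unclass(ttest)),
      file.path(out_dir, "longitudinal.json")
    )
  }

  artifacts <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("jaescore")),
    config = config_as_list(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)) |>
                          setNames(artifacts))
  )
  write_report_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, features = features, loso = loso,
                 ranking = ranking, heatmap = heatmap, paired = paired,
                 ttest = ttest, out_dir = out_dir))
}
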