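#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_tile geom_col
#'   geom_line geom_point geom_path geom_abline labs scale_fill_viridis_c
#'   coord_flip theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot the joint health score distribution from a LOSO evaluation
#'
#' Histogram of per-subject joint health scores colored by true group, with
#' the decision threshold marked; the classifier separates the groups when
#' the two distributions sit on opposite sides of the threshold.
#'
#' @param object a `jae_loso`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot jae_loso
#' @export
autoplot.jae_loso <- function(object, bins = 20, ...) {
  d <- dplyr::mutate(object$subjects,
                     group = ifelse(.data$label == 1, "JIA", "healthy"))
  ggplot(d, aes(x = .data$score, fill = .data$group)) +
    geom_histogram(bins = bins, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    labs(x = "joint health score (mean cycle probability of JIA)",
         y = "subjects", fill = NULL) +
    theme_minimal()
}

#' Plot the ROC curve of a metrics object
#'
#' @param object a `jae_metrics`.
#' @param ... unused.
#' @method autoplot jae_metrics
#' @export
autoplot.jae_metrics <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_path() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC, AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot a feature importance ranking
#'
#' @param object a `jae_ranking`.
#' @param top_n how many top features to show.
#' @param ... unused.
#' @method autoplot jae_ranking
#' @export
autoplot.jae_ranking <- function(object, top_n = 20, ...) {
  d <- head(object, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$magnitude)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "|coefficient| (standardized features)") +
    theme_minimal()
}

#' Plot the feature-by-cycle accuracy grid
#'
#' @param object a `jae_heatmap`.
#' @param ... unused.
#' @method autoplot jae_heatmap
#' @export
autoplot.jae_heatmap <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$n_cycles, y = .data$n_features,
                          fill = .data$accuracy)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "cycles used at test time", y = "top-ranked features used",
         fill = "accuracy") +
    theme_minimal()
}

#' Plot paired baseline/follow-up joint health scores
#'
#' One line per subject from the baseline score to the follow-up score;
#' successful treatment shows as lines dropping toward the healthy range.
#'
#' @param object a `jae_paired`.
#' @param ... unused.
#' @method autoplot jae_paired
#' @export
autoplot.jae_paired <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("baseline", "followup"),
                           names_to = "visit", values_to = "score")
  ggplot(d, aes(x = .data$visit, y = .data$score, group = .data$subject_id)) +
    geom_line(linetype = "dashed", alpha = 0.6) +
    geom_point() +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "joint health score") +
    theme_minimal()
}

#' Plot one session's waveform and knee angle
#'
#' @param cohort a `jae_cohort`.
#' @param subject_id,visit,channel which recording to show.
#' @param max_seconds plot at most this many seconds of audio.
#' @return a ggplot with the audio waveform and the (rescaled) knee angle
#'   overlay.
#' @export
plot_session <- function(cohort, subject_id, visit = "baseline",
                         channel = NULL, max_seconds = 12) {
  ses <- dplyr::filter(cohort, .data$subject_id == .env$subject_id,
                       .data$visit == .env$visit)
  if (nrow(ses) == 0) stop_invalid("no such session")
  audio <- ses$audio[[1]]
  channel <- channel %||% names(audio)[1]
  x <- as.numeric(audio[[channel]])
  fs <- ses$fs_audio[1]
  n <- min(length(x), round(max_seconds * fs))
  wav <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, value = x[seq_len(n)])
  mot <- ses$motion[[1]]
  mot <- mot[mot$time_s <= n / fs, ]
  scale <- max(abs(wav$value))
  ang <- tibble::tibble(
    time_s = mot$time_s,
    value = (mot$angle_deg - min(mot$angle_deg)) /
      max(diff(range(mot$angle_deg)), 1e-9) * 2 * scale - scale
  )
  ggplot(wav, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.2) +
    geom_line(data = ang, color = "red", alpha = 0.7) +
    labs(x = "time (s)", y = "acceleration (a.u.) / knee angle (rescaled, red)",
         title = paste(subject_id, visit, channel)) +
    theme_minimal()
}
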