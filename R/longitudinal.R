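#' Score paired baseline and follow-up sessions
#'
#' For every subject with a follow-up session, a logistic model is trained on
#' baseline rows only -- by default excluding the scored subject's own
#' baseline rows as well, so the score is free of identity leakage
#' (`protocol = "loso"`). `protocol = "cohort_exclusion"` instead trains one
#' model per subject on the baseline rows of all subjects outside the
#' follow-up cohort, reproducing the protocol of training on all subjects not
#' in the longitudinal group. Follow-up rows are never used for training
#' under either protocol. Both visits are scored as the mean predicted
#' probability of the arthritic class over the subject's rows, and the delta
#' (baseline minus follow-up) is the quantity expected to be positive under
#' successful treatment.
#'
#' @param x feature matrix tibble containing baseline and follow-up rows.
#' @param ridge ridge penalty for [fit_logistic()].
#' @param protocol training-set protocol, see Details.
#' @return a `jae_paired` tibble: `subject_id`, `baseline`, `followup`,
#'   `delta`.
#' @export
score_pairs <- function(x, ridge = 1e-4,
                        protocol = c("loso", "cohort_exclusion")) {
  protocol <- match.arg(protocol)
  base <- dplyr::filter(x, .data$visit == "baseline", !is.na(.data$label))
  fup <- dplyr::filter(x, .data$visit == "followup")
  if (nrow(fup) == 0L) stop_invalid("no follow-up rows present")
  fup_ids <- unique(fup$subject_id)
  missing_base <- setdiff(fup_ids, unique(base$subject_id))
  if (length(missing_base) > 0L) {
    stop_invalid(paste("follow-up subject(s) without baseline rows:",
                       paste(missing_base, collapse = ", ")))
  }

  rows <- purrr::map(fup_ids, function(sid) {
    excluded <- if (protocol == "loso") sid else fup_ids
    train <- dplyr::filter(base, !.data$subject_id %in% excluded)
    if (length(unique(train$label)) < 2L) {
      abort(sprintf("training set for subject %s lost a class", sid),
            class = "jae_invalid_training_set")
    }
    st <- standardize_fit(train)
    model <- fit_logistic(standardize_apply(st, train), train$label, ridge = ridge)
    score_of <- function(rows_df) {
      mean(predict(model, standardize_apply(st, rows_df)))
    }
    tibble::tibble(
      subject_id = sid,
      baseline = score_of(dplyr::filter(base, .data$subject_id == sid)),
      followup = score_of(dplyr::filter(fup, .data$subject_id == sid))
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(delta = .data$baseline - .data$followup)
  class(out) <- c("jae_paired", class(out))
  attr(out, "protocol") <- protocol
  out
}

#' One-tailed paired t-test on score deltas
#'
#' Tests whether joint health scores drop from baseline to follow-up:
#' `t = mean(delta) / (sd(delta) / sqrt(n))` with the sample (n-1) standard
#' deviation, against the one-sided alternative that the mean delta is
#' positive; the p-value is the upper tail of the Student-t distribution with
#' `n - 1` degrees of freedom. Zero-variance deltas with a nonzero mean give
#' `t = +-Inf` and a p-value of 0 or 1 (flagged as degenerate); all-zero
#' deltas give `t = 0`, `p = 0.5`.
#'
#' @param deltas numeric vector of per-subject score drops (baseline minus
#'   follow-up), or a `jae_paired` tibble.
#' @return a `jae_ttest` list: `t_statistic`, `dof`, `p_value`, `mean_delta`,
#'   `sd_delta`, `n`, `degenerate`.
#' @export
#' @examples
#' paired_one_tailed_ttest(c(0.6, 0.7, 0.55, 0.62))
paired_one_tailed_ttest <- function(deltas) {
  if (inherits(deltas, "jae_paired")) deltas <- deltas$delta
  if (!is.numeric(deltas) || anyNA(deltas)) stop_invalid("`deltas` must be numeric and complete")
  n <- length(deltas)
  if (n < 2L) stop_invalid("at least 2 paired observations are required")
  m <- mean(deltas)
  s <- sd(deltas)
  degenerate <- s == 0
  t_stat <- if (degenerate) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(n))
  }
  p <- pt(t_stat, df = n - 1, lower.tail = FALSE)
  structure(
    list(t_statistic = t_stat, dof = n - 1L, p_value = p,
         mean_delta = m, sd_delta = s, n = n, degenerate = degenerate,
         alternative = "mean delta > 0"),
    class = "jae_ttest"
  )
}

#' @export
print.jae_ttest <- function(x, ...) {
  cat(sprintf("<jae_ttest> one-tailed paired t-test: t = %.3f, dof = %d, p = %.3g\n",
              x$t_statistic, x$dof, x$p_value))
  cat(sprintf("  mean delta %.3f (sd %.3f), n = %d%s\n", x$mean_delta, x$sd_delta,
              x$n, if (x$degenerate) " [degenerate: zero-variance deltas]" else ""))
  invisible(x)
}
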