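#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted logistic model
#'
#' @param x a `jae_model`.
#' @param ... unused.
#' @return tibble with one row per term (`(Intercept)` first): `term`,
#'   `estimate`, `magnitude`.
#' @method tidy jae_model
#' @export
tidy.jae_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    magnitude = abs(c(x$intercept, unname(x$coefficients)))
  )
}

#' @rdname tidy.jae_model
#' @return for `glance()`: a one-row tibble of fit summaries.
#' @method glance jae_model
#' @export
glance.jae_model <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs, n_features = length(x$coefficients),
    log_lik = x$log_lik, ridge = x$ridge,
    converged = x$converged, iterations = x$iterations
  )
}

#' Tidy leave-one-subject-out results
#'
#' `tidy()` returns the per-subject joint health scores and class calls;
#' `glance()` returns the one-row cycle- and subject-level metric summary.
#'
#' @param x a `jae_loso`.
#' @param ... unused.
#' @method tidy jae_loso
#' @export
tidy.jae_loso <- function(x, ...) x$subjects

#' @rdname tidy.jae_loso
#' @method glance jae_loso
#' @export
glance.jae_loso <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_subjects = nrow(x$subjects), n_cycles = m$n,
    cycle_accuracy = m$accuracy, error_rate = m$error_rate,
    sensitivity = m$sensitivity, specificity = m$specificity,
    ppv = m$ppv, npv = m$npv, auc = m$auc,
    subject_accuracy_mean_rule = m$subject_accuracy_mean_rule,
    subject_accuracy_majority_rule = m$subject_accuracy_majority_rule,
    tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
    threshold = x$threshold, ridge = x$ridge
  )
}

#' Tidy a paired longitudinal result
#'
#' @param x a `jae_paired` or `jae_ttest`.
#' @param ... unused.
#' @method tidy jae_ttest
#' @export
tidy.jae_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_delta, statistic = x$t_statistic,
    p.value = x$p_value, parameter = x$dof,
    alternative = x$alternative
  )
}

#' @rdname tidy.jae_ttest
#' @method glance jae_ttest
#' @export
glance.jae_ttest <- function(x, ...) {
  tibble::tibble(
    statistic = x$t_statistic, p.value = x$p_value, parameter = x$dof,
    mean_delta = x$mean_delta, sd_delta = x$sd_delta, n = x$n,
    degenerate = x$degenerate
  )
}

#' Tidy a heatmap result into its long accuracy grid
#'
#' @param x a `jae_heatmap`.
#' @param ... unused.
#' @method tidy jae_heatmap
#' @export
tidy.jae_heatmap <- function(x, ...) x$grid
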