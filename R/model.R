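#' Logistic function
#'
#' Maps any real number to a probability in (0, 1) via `1 / (1 + exp(-z))`,
#' computed in a form that is numerically stable for `|z|` up to several
#' hundred.
#'
#' @param z numeric vector.
#' @return probabilities, same length as `z`.
#' @export
#' @examples
#' logistic(0)        # 0.5
#' logistic(log(3))   # 0.75
logistic <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

as_design <- function(x) {
  if (is.data.frame(x)) as.matrix(x[feature_columns(x)]) else as.matrix(x)
}

#' Fit a logistic-regression classifier by quasi-Newton maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of a linear logistic model by BFGS
#' quasi-Newton iteration with an analytic gradient. A small ridge penalty on
#' the coefficients (never the intercept) is applied by default: on cleanly
#' separable data the pure maximum-likelihood estimate diverges, and the tiny
#' penalty keeps the optimum finite without measurably changing predictions;
#' `ridge = 0` recovers the unpenalized fit. Convergence is declared when the
#' gradient infinity-norm falls below 1e-6; otherwise the best iterate is
#' returned with a warning.
#'
#' @param x design matrix or feature tibble (metadata columns ignored);
#'   expected to be standardized for interpretable coefficient magnitudes.
#' @param y 0/1 labels (1 = arthritic class).
#' @param ridge ridge penalty weight (>= 0) on the coefficients.
#' @param max_iter BFGS iteration cap.
#' @return a `jae_model` with `intercept`, `coefficients` (named),
#'   `converged`, `iterations`, `log_lik` and the column names.
#' @export
fit_logistic <- function(x, y, ridge = 1e-4, max_iter = 500L) {
  X <- as_design(x)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_invalid("length(y) must equal nrow(x)")
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("labels must be 0/1 with no unknowns", class = "jae_invalid_training_set")
  }
  if (length(unique(y)) < 2L) {
    abort("training set must contain both classes", class = "jae_invalid_training_set")
  }
  check_scalar_number(ridge, "ridge", min = 0)
  p <- ncol(X)

  # negative penalized log-likelihood; par = c(b0, beta)
  nll <- function(par) {
    z <- par[1] + drop(X %*% par[-1])
    # log(1 + exp(z)) computed stably
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    -sum(y * z - lse) + 0.5 * ridge * sum(par[-1]^2)
  }
  grad <- function(par) {
    z <- par[1] + drop(X %*% par[-1])
    r <- logistic(z) - y
    c(sum(r), drop(crossprod(X, r)) + ridge * par[-1])
  }

  fit <- stats::optim(rep(0, p + 1L), nll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))

  # Newton polish: BFGS can stall on a flat likelihood before reaching the
  # gradient tolerance; a few damped Newton steps finish the job
  par <- fit$par
  f_cur <- nll(par)
  iter_newton <- 0L
  while (max(abs(grad(par))) >= 1e-6 && iter_newton < 100L) {
    z <- par[1] + drop(X %*% par[-1])
    w <- pmax(logistic(z) * (1 - logistic(z)), 1e-12)
    Xa <- cbind(1, X)
    H <- crossprod(Xa, Xa * w) + diag(c(1e-10, rep(ridge, p)))
    step <- tryCatch(solve(H, grad(par)), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      f_new <- nll(cand)
      if (is.finite(f_new) && f_new <= f_cur) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
    par <- par - alpha * step
    f_cur <- nll(par)
    iter_newton <- iter_newton + 1L
  }
  fit$par <- par
  fit$value <- f_cur
  fit$counts[["function"]] <- fit$counts[["function"]] + iter_newton

  g <- grad(fit$par)
  converged <- max(abs(g)) < 1e-6
  if (!converged) {
    warn(sprintf("quasi-Newton fit did not reach gradient tolerance (|grad|_inf = %.2e); returning best iterate",
                 max(abs(g))), class = "jae_nonconvergence")
  }
  cols <- colnames(X) %||% paste0("x", seq_len(p))
  structure(
    list(
      intercept = fit$par[1],
      coefficients = setNames(fit$par[-1], cols),
      column_names = cols,
      ridge = ridge,
      converged = converged,
      iterations = fit$counts[["function"]],
      log_lik = -fit$value - 0.5 * ridge * sum(fit$par[-1]^2),
      n_obs = nrow(X),
      stats = NULL
    ),
    class = "jae_model"
  )
}

#' @export
print.jae_model <- function(x, ...) {
  cat("<jae_model> logistic regression:", length(x$coefficients), "features,",
      x$n_obs, "rows;", if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Predict class probabilities from a fitted model
#'
#' @param object a `jae_model`.
#' @param newdata design matrix or feature tibble with the model's columns;
#'   must already be standardized with the training-fold statistics.
#' @param ... unused.
#' @return probability vector.
#' @export
predict.jae_model <- function(object, newdata, ...) {
  X <- as_design(newdata)
  if (!is.null(colnames(X))) X <- X[, object$column_names, drop = FALSE]
  logistic(object$intercept + drop(X %*% object$coefficients))
}

subject_label <- function(score, threshold = 0.5) {
  # ties at the threshold go to healthy
  ifelse(score > threshold, 1, 0)
}

#' Leave-one-subject-out evaluation with a joint health score
#'
#' For every baseline subject all of that subject's rows are removed, the
#' remaining matrix is standardized (statistics fit on it alone), a logistic
#' model is fitted, and the held-out subject's rows are standardized with the
#' training statistics and scored. Follow-up rows are never part of any
#' training fold. Each cycle row gets a predicted probability of the
#' arthritic class; the subject's joint health score is the arithmetic mean
#' of its row probabilities. A subject is called arthritic when its score
#' exceeds the threshold (ties go to healthy); the majority-of-cycle-labels
#' call is reported alongside (even splits also go to healthy).
#'
#' @param x feature matrix tibble (unstandardized; may include follow-up
#'   rows, which are ignored here).
#' @param ridge,threshold model penalty and decision threshold.
#' @return a `jae_loso` object: `predictions` (per-row tibble), `subjects`
#'   (per-subject scores and calls), `metrics` (a `jae_metrics` from
#'   [compute_metrics()] on cycle probabilities), and `folds` (per-fold
#'   standardization statistics and fitted models).
#' @export
loso_evaluate <- function(x, ridge = 1e-4, threshold = 0.5) {
  base <- dplyr::filter(x, .data$visit == "baseline", !is.na(.data$label))
  subj <- dplyr::distinct(base, .data$subject_id, .data$label)
  if (any(duplicated(subj$subject_id))) stop_invalid("a subject has inconsistent labels")
  if (length(unique(subj$label)) < 2L || min(table(subj$label)) < 2L) {
    stop_invalid("at least 2 subjects per class are required for leave-one-subject-out evaluation")
  }

  folds <- list()
  preds <- purrr::map(subj$subject_id, function(sid) {
    train <- dplyr::filter(base, .data$subject_id != sid)
    test <- dplyr::filter(base, .data$subject_id == sid)
    if (length(unique(train$label)) < 2L) {
      abort(sprintf("training fold for subject %s lost a class", sid),
            class = "jae_invalid_training_set")
    }
    st <- standardize_fit(train)
    model <- fit_logistic(standardize_apply(st, train), train$label, ridge = ridge)
    model$stats <- st
    folds[[sid]] <<- list(stats = st, model = model)
    p <- predict(model, standardize_apply(st, test))
    dplyr::mutate(test[jae_meta_cols], p_predicted = p,
                  cycle_label = as.integer(p > threshold))
  })
  predictions <- dplyr::bind_rows(preds)

  subjects <- predictions |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      score = mean(.data$p_predicted),
      frac_jia_cycles = mean(.data$cycle_label),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      label_mean_rule = subject_label(.data$score, threshold),
      label_majority_rule = subject_label(.data$frac_jia_cycles, 0.5)
    )

  metrics <- compute_metrics(predictions$label, predictions$p_predicted, threshold)
  metrics$subject_accuracy_mean_rule <- mean(subjects$label_mean_rule == subjects$label)
  metrics$subject_accuracy_majority_rule <- mean(subjects$label_majority_rule == subjects$label)

  structure(
    list(predictions = predictions, subjects = subjects, metrics = metrics,
         folds = folds, threshold = threshold, ridge = ridge),
    class = "jae_loso"
  )
}

#' @export
print.jae_loso <- function(x, ...) {
  m <- x$metrics
  cat("<jae_loso>", nrow(x$subjects), "subjects,", nrow(x$predictions), "cycles\n")
  cat(sprintf("  cycle accuracy %.1f%%, AUC %.3f, sens %.1f%%, spec %.1f%%\n",
              100 * m$accuracy, m$auc, 100 * m$sensitivity, 100 * m$specificity))
  cat(sprintf("  subject accuracy: %.1f%% (mean rule), %.1f%% (majority rule)\n",
              100 * m$subject_accuracy_mean_rule, 100 * m$subject_accuracy_majority_rule))
  invisible(x)
}

#' Classification metrics from probabilities and binary truth
#'
#' Computes the confusion matrix at the given threshold (positive class = 1),
#' the derived rates (sensitivity, specificity, PPV, NPV, accuracy, error
#' rate) and the ROC curve by sweeping every unique probability as a
#' threshold, with area under the curve by the trapezoid rule.
#'
#' @param truth 0/1 vector.
#' @param prob probability vector, same length.
#' @param threshold decision threshold (a row is called positive when
#'   `prob > threshold`).
#' @return a `jae_metrics` list (includes a `roc` tibble with `fpr`, `tpr`).
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc  # 1
compute_metrics <- function(truth, prob, threshold = 0.5) {
  if (length(truth) == 0L) stop_invalid("empty input")
  if (length(truth) != length(prob)) stop_invalid("`truth` and `prob` lengths differ")
  if (!all(truth %in% c(0, 1))) stop_invalid("`truth` must be binary 0/1")
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b

  # ROC: sweep thresholds from above max(prob) down to below min(prob)
  cuts <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  roc <- purrr::map_dfr(cuts, function(ct) {
    p1 <- prob >= ct
    tibble::tibble(
      threshold = ct,
      fpr = if (n_neg == 0) 0 else sum(p1 & truth == 0) / n_neg,
      tpr = if (n_pos == 0) 0 else sum(p1 & truth == 1) / n_pos
    )
  })
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)

  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = (tp + tn) / length(truth),
      error_rate = 1 - (tp + tn) / length(truth),
      sensitivity = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn),
      auc = auc,
      roc = roc,
      threshold = threshold,
      n = length(truth)
    ),
    class = "jae_metrics"
  )
}

#' @export
print.jae_metrics <- function(x, ...) {
  cat(sprintf("<jae_metrics> n=%d  acc %.3f  sens %.3f  spec %.3f  AUC %.3f\n",
              x$n, x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
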