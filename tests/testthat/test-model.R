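test_that("logistic function satisfies its closed forms and identities", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(log(3)), 0.75)
  z <- c(-700, -5, -0.1, 0.1, 5, 700)
  expect_equal(logistic(z) + logistic(-z), rep(1, length(z)))
  expect_true(all(logistic(z) >= 0 & logistic(z) <= 1))
})

test_that("quasi-Newton fit recovers a separable 1-D signal and is self-consistent", {
  set.seed(1)
  y <- rep(c(0, 1), each = 50)
  x <- matrix(y + rnorm(100, 0, 0.1), ncol = 1, dimnames = list(NULL, "f"))
  m <- fit_logistic(x, y, ridge = 1e-4)
  expect_gt(m$coefficients[["f"]], 0)
  p <- predict(m, x)
  expect_equal(as.integer(p > 0.5), y)
  # predictions equal the logistic mapping evaluated with the model's own terms
  expect_equal(p, logistic(m$intercept + drop(x %*% m$coefficients)))
})

test_that("flipping the labels negates the coefficient vector (ridge fit)", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, logistic(X %*% c(1, -0.5, 0)))
  m1 <- fit_logistic(X, y, ridge = 1e-3)
  m2 <- fit_logistic(X, 1 - y, ridge = 1e-3)
  expect_equal(m1$coefficients, -m2$coefficients, tolerance = 1e-6)
  expect_equal(m1$intercept, -m2$intercept, tolerance = 1e-6)
})

test_that("unpenalized fit matches the glm maximum-likelihood oracle", {
  set.seed(2)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, logistic(0.3 + 0.8 * x1 - 0.5 * x2))
  own <- fit_logistic(cbind(x1 = x1, x2 = x2), y, ridge = 0)
  ref <- stats::glm(y ~ x1 + x2, family = stats::binomial)
  expect_equal(unname(c(own$intercept, own$coefficients)),
               unname(stats::coef(ref)), tolerance = 1e-6)
})

test_that("degenerate training sets are rejected", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_logistic(X, rep(1, 10)), class = "jae_invalid_training_set")
  expect_error(fit_logistic(X, c(rep(0, 5), rep(NA, 5))),
               class = "jae_invalid_training_set")
})

test_that("LOSO separates a strong-effect cohort and scores stay within cycle bounds", {
  res <- cached("strong_loso", loso_evaluate(strong_features()))
  expect_gte(res$metrics$accuracy, 0.9)
  expect_equal(res$metrics$subject_accuracy_mean_rule, 1.0)
  expect_equal(res$metrics$subject_accuracy_majority_rule, 1.0)
  # aggregation consistency: subject score inside its own cycle probabilities
  bounds <- res$predictions |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(lo = min(p_predicted), hi = max(p_predicted))
  merged <- dplyr::left_join(res$subjects, bounds, by = "subject_id")
  expect_true(all(merged$score >= merged$lo & merged$score <= merged$hi))
})

test_that("the subject decision rule sends threshold ties to healthy", {
  expect_equal(jaescore:::subject_label(0.5), 0)   # mean(p) <= 0.5 -> healthy
  expect_equal(jaescore:::subject_label(mean(c(0.4, 0.6))), 0)
  expect_equal(jaescore:::subject_label(0.5000001), 1)
})

test_that("held-out subjects never leak into fold standardization or fitting", {
  X <- small_features()
  sid <- X$subject_id[1]
  res1 <- loso_evaluate(X)
  # perturb only the held-out subject's rows
  X2 <- X
  cols <- setdiff(names(X), jaescore:::jae_meta_cols)
  idx <- X2$subject_id == sid
  for (j in cols) X2[[j]][idx] <- X2[[j]][idx] * 3 + 1
  res2 <- loso_evaluate(X2)
  expect_identical(res1$folds[[sid]]$stats$mean, res2$folds[[sid]]$stats$mean)
  expect_identical(res1$folds[[sid]]$stats$sd, res2$folds[[sid]]$stats$sd)
  expect_identical(res1$folds[[sid]]$model$coefficients,
                   res2$folds[[sid]]$model$coefficients)
})

test_that("LOSO rejects cohorts that cannot support per-class folds", {
  X <- small_features()
  expect_error(loso_evaluate(dplyr::filter(X, label == 1)),
               class = "jae_invalid_argument")
})

test_that("confusion metrics reproduce hand-computed values", {
  truth <- c(rep(1, 3), 0, rep(0, 4), rep(1, 2))
  prob <- c(rep(0.9, 3), 0.9, rep(0.1, 4), rep(0.1, 2))  # TP=3 FP=1 TN=4 FN=2
  m <- compute_metrics(truth, prob)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 4); expect_equal(m$fn, 2)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 4 / 6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$error_rate, 0.3)
  # metric algebra from stored counts
  expect_equal(m$accuracy, (m$tp + m$tn) / m$n)
})

test_that("ROC limits: perfect separation gives AUC 1, constant scores give 0.5", {
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.4, 4))$auc, 0.5)
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  set.seed(11)
  truth <- rbinom(200, 1, 0.4)
  prob <- pmin(pmax(truth * 0.3 + runif(200, 0, 0.8), 0), 1)
  own <- compute_metrics(truth, prob)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(truth, prob, direction = "<")))
  expect_equal(own, ref, tolerance = 1e-12)
})

test_that("a null cohort (zero click effect) classifies at chance", {
  acc <- vapply(1:10, function(s) {
    X <- fast_features(fast_spec(n_jia = 6, n_healthy = 6, cycles = 5,
                                 channels = 2, amplitude = 0, seed = 100 + s))
    loso_evaluate(X)$metrics$accuracy
  }, numeric(1))
  expect_gt(mean(acc), 0.4)
  expect_lt(mean(acc), 0.6)
})

test_that("tidy and glance summarize fits and evaluations", {
  res <- cached("strong_loso", loso_evaluate(strong_features()))
  td <- tidy(res)
  gl <- glance(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  expect_equal(gl$n_subjects, 16)
  expect_true(all(c("cycle_accuracy", "auc", "sensitivity", "specificity") %in% names(gl)))
  m <- res$folds[[1]]$model
  expect_equal(nrow(tidy(m)), length(m$coefficients) + 1)
  expect_true(glance(m)$converged)
})
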