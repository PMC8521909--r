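longitudinal_features <- function(seed, followup_profile = NULL) {
  fast_features(fast_spec(n_jia = 5, n_healthy = 5, n_followup = 5,
                          cycles = 4, channels = 2, amplitude = 12,
                          seed = seed, followup_profile = followup_profile))
}

test_that("attenuated follow-up clicks lower every subject's score", {
  X <- cached("long_attenuated", longitudinal_features(seed = 31))
  pr <- score_pairs(X)
  expect_equal(nrow(pr), 5)
  expect_true(all(pr$delta > 0))
  expect_true(all(pr$baseline >= 0 & pr$baseline <= 1))
  expect_true(all(pr$followup >= 0 & pr$followup <= 1))
})

test_that("identical follow-up profile gives deltas centered at zero", {
  same_profile <- fast_profiles(amplitude = 12)$jia
  deltas <- unlist(lapply(1:10, function(s) {
    score_pairs(longitudinal_features(seed = 500 + s,
                                      followup_profile = same_profile))$delta
  }))
  expect_lt(abs(mean(deltas)), 0.1)
})

test_that("the cohort-exclusion protocol trains outside the follow-up group", {
  # needs arthritic subjects outside the follow-up cohort to retain both
  # classes in the training set
  X <- fast_features(fast_spec(n_jia = 6, n_healthy = 4, n_followup = 3,
                               cycles = 3, channels = 2, amplitude = 12,
                               seed = 33))
  pr <- score_pairs(X, protocol = "cohort_exclusion")
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$delta > 0))
  # with every arthritic subject in the follow-up group the protocol must fail
  X5 <- cached("long_attenuated", longitudinal_features(seed = 31))
  expect_error(score_pairs(X5, protocol = "cohort_exclusion"),
               class = "jae_invalid_training_set")
})

test_that("follow-up subjects without baseline rows are rejected", {
  X <- cached("long_attenuated", longitudinal_features(seed = 31))
  no_base <- dplyr::filter(X, !(visit == "baseline" & subject_id == "jia01"))
  expect_error(score_pairs(no_base), class = "jae_invalid_argument")
})

test_that("the paired one-tailed t statistic matches its definition and oracles", {
  d <- c(1, 2, 3, 4)
  r <- paired_one_tailed_ttest(d)
  expect_equal(r$dof, 3L)
  expect_equal(r$t_statistic, mean(d) / (sd(d) / sqrt(4)))
  # quadrature oracle for the Student-t upper tail
  expect_lt(abs(r$p_value - oracle_t_tail(r$t_statistic, r$dof)), 1e-8)
  # established implementation as a second oracle
  ref <- stats::t.test(d, mu = 0, alternative = "greater")
  expect_equal(r$t_statistic, unname(ref$statistic))
  expect_equal(r$p_value, unname(ref$p.value))
})

test_that("t-test handles degenerate deltas and sign equivariance", {
  z <- paired_one_tailed_ttest(rep(0, 6))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 0.5)

  const <- paired_one_tailed_ttest(rep(0.4, 5))
  expect_true(const$degenerate)
  expect_equal(const$t_statistic, Inf)
  expect_equal(const$p_value, 0)

  d <- c(0.2, 0.5, 0.1, 0.9, 0.3)
  pos <- paired_one_tailed_ttest(d)
  neg <- paired_one_tailed_ttest(-d)
  expect_equal(neg$t_statistic, -pos$t_statistic)
  expect_equal(neg$p_value, 1 - pos$p_value)

  expect_error(paired_one_tailed_ttest(0.5), class = "jae_invalid_argument")
})

test_that("ten pairs give nine degrees of freedom", {
  r <- paired_one_tailed_ttest(seq(0.1, 1, by = 0.1))
  expect_equal(r$dof, 9L)
  expect_equal(r$n, 10L)
})
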