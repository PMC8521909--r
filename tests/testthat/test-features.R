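test_that("pure-tone frame features match closed forms", {
  fs <- 25000
  n <- 10000                               # one 400 ms frame
  frame <- sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  f <- frame_features(frame, fs)
  expect_lt(abs(f[["spectral_centroid"]] - 1000) / 1000, 0.01)
  expect_lt(f[["spectral_spread"]], 50)
  # 2 sign changes per period: 2 * 1000 crossings/s (allow one sample's worth)
  expect_lt(abs(f[["zcr"]] - 2000), 2000 / n + 3)
  expect_equal(f[["rms"]], sqrt(mean(frame^2)))
  expect_equal(f[["energy"]], sum(frame^2))
})

test_that("white-noise frames reach near-maximal spectral entropy", {
  # a flat spectrum maximizes entropy at log2(n_bins); periodogram
  # fluctuation costs a constant ~0.6 bits, so the relative gap shrinks
  # with frame length -- checked at a long analysis frame
  fs <- 32768
  n <- 32768
  n_bins <- n %/% 2 + 1
  h <- vapply(1:50, function(s) {
    set.seed(s)
    frame_features(rnorm(n), fs)[["spectral_entropy"]]
  }, numeric(1))
  expect_lt(max(abs(h - log2(n_bins))) / log2(n_bins), 0.05)
})

test_that("spectral features agree with a brute-force DFT oracle", {
  set.seed(99)
  fs <- 2000
  for (i in 1:20) {
    prev <- rnorm(256)
    frame <- rnorm(256) + sin(2 * pi * runif(1, 100, 900) * (0:255) / fs)
    got <- frame_features(frame, fs,
                          prev = jaescore:::frame_context(prev, fs)$mag_norm)
    want <- oracle_spectral(frame, fs, prev_frame = prev)
    for (nm in names(want)) {
      expect_lt(rel_diff(got[[nm]], want[[nm]]), 1e-8)
    }
  }
})

test_that("all-zero frames yield defined (zero) features, never NaN", {
  f <- frame_features(rep(0, 512), 2000)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f[c("energy", "rms", "spectral_centroid", "spectral_entropy")]),
               rep(0, 4))
})

test_that("cycle summaries compute mean / population SD / CoV across frames", {
  reg <- jae_registry()
  p <- length(reg$base_features)
  # two frames with values {1, 3} in every base feature
  fm <- rbind(rep(1, p), rep(3, p))
  out <- cycle_features(fm, reg)
  expect_equal(length(out), 3 * p)
  expect_equal(unname(out[grepl("_mean$", names(out))]), rep(2, p))
  expect_equal(unname(out[grepl("_sd$", names(out))]), rep(1, p))    # n-denominator SD
  expect_equal(unname(out[grepl("_cov$", names(out))]), rep(0.5, p), tolerance = 1e-9)

  same <- rbind(rep(2, p), rep(2, p), rep(2, p))
  out2 <- cycle_features(same, reg)
  expect_true(all(out2[grepl("_(sd|cov)$", names(out2))] == 0))

  single <- cycle_features(matrix(seq_len(p), nrow = 1), reg)
  expect_equal(unname(single[grepl("_mean$", names(single))]), as.numeric(seq_len(p)))
  expect_true(all(single[grepl("_sd$", names(single))] == 0))

  expect_error(cycle_features(fm[0, , drop = FALSE], reg), class = "jae_invalid_argument")
})

test_that("scale-invariant features ignore gain; energy scales quadratically", {
  set.seed(7)
  fs <- 4000
  m <- generate_motion_trace(2, 4, 50, seed = 3)
  prof <- class_profile("jia", click_freq_range = c(500, 1500))
  x <- as.numeric(generate_audio(prof, m, fs, seed = 3))
  cyc <- x[1:(4 * fs)]
  feats <- function(v) {
    frames <- frame_cycle(v, 0.4, fs)
    prev <- NULL
    out <- NULL
    for (i in seq_len(nrow(frames))) {
      ctx <- jaescore:::frame_context(frames[i, ], fs, prev)
      out <- rbind(out, frame_features(frames[i, ], fs, prev = prev))
      prev <- ctx$mag_norm
    }
    cycle_features(out)
  }
  f1 <- feats(cyc)
  f3 <- feats(3 * cyc)
  invariant <- c("zcr", "signal_entropy", "spectral_centroid", "spectral_spread",
                 "spectral_rolloff", "spectral_entropy", "spectral_flux")
  for (nm in paste0(invariant, "_mean")) {
    expect_lt(rel_diff(f3[[nm]], f1[[nm]]), 1e-6)
  }
  for (nm in grep("_cov$", names(f1), value = TRUE)) {
    expect_lt(rel_diff(f3[[nm]], f1[[nm]]), 1e-6)
  }
  expect_lt(rel_diff(f3[["energy_mean"]], 9 * f1[["energy_mean"]]), 1e-6)
})

test_that("feature matrix has one row per subject x channel x cycle", {
  spec <- fast_spec(n_jia = 1, n_healthy = 1, cycles = 10, channels = 4, seed = 8)
  coh <- generate_cohort(spec)
  X <- build_feature_matrix(coh[coh$subject_id == "jia01", ], band = c(250, 1800))
  expect_equal(nrow(X), 40)                # 4 channels x 10 cycles
  expect_equal(length(feature_cols <- setdiff(names(X), jaescore:::jae_meta_cols)), 30)
  expect_false(anyNA(X[feature_cols]))
  # byte-identical reassembly
  X2 <- build_feature_matrix(coh[coh$subject_id == "jia01", ], band = c(250, 1800))
  expect_identical(X, X2)
})

test_that("standardization is fold-local, linear, and guards constant columns", {
  X <- small_features()
  st <- standardize_fit(X)
  Z <- standardize_apply(st, X)
  cols <- setdiff(names(Z), jaescore:::jae_meta_cols)
  for (j in cols[1:5]) {
    expect_lt(abs(mean(Z[[j]])), 1e-9)
    expect_lt(abs(var(Z[[j]]) - 1), 1e-9)
  }
  # held-out rows shifted by +c move by c/sd under the training stats
  held <- X[1:10, ]
  j <- cols[1]
  shifted <- held
  shifted[[j]] <- shifted[[j]] + 2.5
  z0 <- standardize_apply(st, held)
  z1 <- standardize_apply(st, shifted)
  expect_equal(z1[[j]] - z0[[j]], rep(2.5 / st$sd[[j]], 10))

  # constant column -> epsilon guard, all-zero output, warning
  Xc <- X
  Xc[[j]] <- 1
  expect_warning(stc <- standardize_fit(Xc), class = "jae_zero_variance")
  expect_true(all(standardize_apply(stc, Xc)[[j]] == 0))
})
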