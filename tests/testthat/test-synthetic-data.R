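test_that("motion trace has the requested duration, cycle count and periodicity", {
  m <- generate_motion_trace(10, 4, 50, seed = 1)
  expect_equal(nrow(m), 2000)             # 10 cycles x 4 s x 50 Hz
  expect_equal(length(attr(m, "cycle_starts")), 10)
  expect_equal(attr(m, "cycle_starts"), seq(1L, 1801L, by = 200L))

  # one jitter-free cycle: first and last samples at the same phase
  # within one sample's worth of angle change
  m1 <- generate_motion_trace(1, 4, 50, seed = 1)
  one_sample_step <- abs(m1$angle_deg[2] - m1$angle_deg[1])
  expect_lt(abs(m1$angle_deg[nrow(m1)] - m1$angle_deg[1]), one_sample_step + 1e-9)

  expect_identical(generate_motion_trace(5, 4, 50, seed = 3, period_jitter = 0.05),
                   generate_motion_trace(5, 4, 50, seed = 3, period_jitter = 0.05))
  expect_error(generate_motion_trace(0, 4, 50), class = "jae_invalid_argument")
  expect_error(generate_motion_trace(5, -1, 50), class = "jae_invalid_argument")
  expect_error(generate_motion_trace(5, 4, 0.4), class = "jae_invalid_argument")
})

test_that("click-free audio is Gaussian noise (moment oracle)", {
  motion <- generate_motion_trace(1, 4, 50, seed = 1)
  prof <- class_profile("healthy", click_freq_range = c(500, 1500))
  x <- generate_audio(prof, motion, fs_audio = 30000, seed = 2)
  expect_gte(length(x), 1e5)
  expect_lt(abs(excess_kurtosis(as.numeric(x))), 0.2)
  expect_lt(abs(sqrt(mean(x^2)) - prof$noise_rms), 0.02)
})

test_that("clicks dominate the noise floor in almost every cycle", {
  motion <- generate_motion_trace(1, 4, 50, seed = 1)
  prof <- class_profile("jia", clicks_per_cycle = 5, click_amplitude = 10,
                        click_freq_range = c(500, 1500))
  exceeds <- vapply(1:100, function(s) {
    x <- generate_audio(prof, motion, fs_audio = 8000, seed = s)
    max(abs(x)) > 5 * prof$noise_rms
  }, logical(1))
  expect_gte(mean(exceeds), 0.99)
})

test_that("audio generation is seed-deterministic and validates Nyquist", {
  motion <- generate_motion_trace(2, 4, 50, seed = 1)
  prof <- class_profile("jia", click_freq_range = c(500, 1500))
  expect_identical(generate_audio(prof, motion, 4000, seed = 9),
                   generate_audio(prof, motion, 4000, seed = 9))
  expect_false(identical(as.numeric(generate_audio(prof, motion, 4000, seed = 9)),
                         as.numeric(generate_audio(prof, motion, 4000, seed = 10))))
  bad <- class_profile("jia", click_freq_range = c(500, 2500))
  expect_error(generate_audio(bad, motion, 4000), class = "jae_invalid_argument")
})

test_that("cohort matches the default study design: 43 baseline + follow-ups", {
  spec <- cohort_spec(
    n_jia = 25, n_healthy = 18, n_followup = 10,
    cycles_per_recording = 1, cycle_period = 1, fs_audio = 4000, fs_motion = 50,
    channels_per_subject = 4, profiles = fast_profiles(), seed = 5
  )
  coh <- generate_cohort(spec)
  expect_equal(sum(coh$visit == "baseline"), 43)
  expect_equal(sum(coh$visit == "followup"), 10)
  expect_equal(table(coh$group_label[coh$visit == "baseline"])[["jia"]], 25)
  expect_equal(table(coh$group_label[coh$visit == "baseline"])[["healthy"]], 18)
  expect_true(all(coh$group_label[coh$visit == "followup"] == "unknown"))
  expect_true(all(vapply(coh$audio, length, integer(1)) == 4L))
  # all channels of a session share length; motion covers the audio
  for (i in c(1, 30, 50)) {
    lens <- vapply(coh$audio[[i]], length, integer(1))
    expect_true(all(lens == lens[1]))
  }
})

test_that("cohorts are reproducible and the master seed isolates waveforms", {
  s1 <- fast_spec(n_jia = 2, n_healthy = 2, cycles = 2, seed = 1)
  s2 <- fast_spec(n_jia = 2, n_healthy = 2, cycles = 2, seed = 2)
  c1a <- generate_cohort(s1)
  c1b <- generate_cohort(s1)
  c2 <- generate_cohort(s2)
  expect_identical(c1a$audio, c1b$audio)
  expect_false(identical(as.numeric(c1a$audio[[1]][[1]]),
                         as.numeric(c2$audio[[1]][[1]])))
  expect_equal(dim(c1a), dim(c2))

  # adding subjects never perturbs existing subjects' waveforms
  s_big <- fast_spec(n_jia = 3, n_healthy = 2, cycles = 2, seed = 1)
  c_big <- generate_cohort(s_big)
  expect_identical(c1a$audio[[1]], c_big$audio[[1]])
})

test_that("cohort spec invariants are enforced", {
  expect_error(fast_spec(n_jia = 2, n_followup = 3), class = "jae_invalid_argument")
  expect_error(cohort_spec(profiles = fast_profiles(), fs_audio = 2500),
               class = "jae_invalid_argument")   # click band above Nyquist
})

test_that("arthritic sessions carry more band-limited energy than healthy ones", {
  spec <- fast_spec(n_jia = 10, n_healthy = 10, cycles = 2, channels = 1,
                    amplitude = 10, seed = 77)
  coh <- generate_cohort(spec)
  energy <- vapply(seq_len(nrow(coh)), function(i) {
    x <- bandpass(as.numeric(coh$audio[[i]][[1]]), coh$fs_audio[i], 250, 1800)
    starts <- coh$cycle_starts[[i]]
    ends <- c(starts[-1] - 1L, length(x))
    mean(vapply(seq_along(starts), function(k) {
      sum(x[starts[k]:ends[k]]^2)
    }, numeric(1)))
  }, numeric(1))
  w <- stats::wilcox.test(energy[coh$group_label == "jia"],
                          energy[coh$group_label == "healthy"],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
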