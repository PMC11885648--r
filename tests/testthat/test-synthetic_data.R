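# Generators: cascade, fGn, EEG, gaze, cohort.

test_that("binomial cascade cells are products of multipliers and conserve mass", {
  # uniform limit
  m <- gen_binomial_cascade(0.5, 10)
  expect_length(m, 1024)
  expect_true(all(abs(m - 2^-10) < 1e-15))

  # depth 3, p = 0.3: cells are products of three factors from {0.3, 0.7};
  # oracle by explicit enumeration of the 8 products
  m3 <- gen_binomial_cascade(0.3, 3)
  oracle <- sort(apply(expand.grid(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7)),
                       1, prod))
  expect_equal(sort(m3), oracle, tolerance = 1e-12)
  expect_equal(max(m3), 0.343)

  for (p in c(0.1, 0.3, 0.45)) {
    for (depth in c(1, 5, 12)) {
      expect_lt(abs(sum(gen_binomial_cascade(p, depth)) - 1), 1e-12)
    }
  }
  expect_error(gen_binomial_cascade(0.3, 25), "depth")
  # randomized variant is seeded and conserves mass
  r1 <- gen_binomial_cascade(0.3, 8, randomize = TRUE, seed = 7)
  r2 <- gen_binomial_cascade(0.3, 8, randomize = TRUE, seed = 7)
  expect_identical(r1, r2)
  expect_lt(abs(sum(r1) - 1), 1e-12)
})

test_that("fGn has the exact autocovariance signature and unit variance", {
  # lag-1 autocorrelation of fGn is 2^(2H-1) - 1
  lag1 <- function(x) stats::cor(x[-1], x[-length(x)])
  r7 <- vapply(1:20, function(s) lag1(gen_fgn(0.7, 4096, seed = s)),
               numeric(1))
  expect_lt(abs(mean(r7) - (2^(2 * 0.7 - 1) - 1)), 0.05)
  r5 <- vapply(1:20, function(s) lag1(gen_fgn(0.5, 4096, seed = s + 50)),
               numeric(1))
  expect_lt(abs(mean(r5)), 0.05)               # white-noise limit
  v <- vapply(1:20, function(s) stats::var(gen_fgn(0.7, 4096, seed = s)),
              numeric(1))
  expect_lt(abs(mean(v) - 1), 0.1)
  expect_identical(gen_fgn(0.8, 256, seed = 3), gen_fgn(0.8, 256, seed = 3))
  expect_error(gen_fgn(1.2, 100))
})

test_that("synthetic EEG plants the alpha-power ratio and artifacts", {
  rec <- gen_synthetic_eeg(60, faa_target = 1.0, seed = 1)
  ep <- reject_amplitude(make_epochs(eeg_bandpass(rec),
                                     channels = c("F3", "F4")))
  fe <- epoch_features(ep)
  expect_lt(abs(mean(fe$faa, na.rm = TRUE) - 1.0), 0.05)

  # F4 alpha amplitude sqrt(10) x F3 == faa target of 1 by construction;
  # with the other bands silenced the shared carrier makes the ratio exact
  rec2 <- gen_synthetic_eeg(
    30, band_amplitudes = list(
      F3 = c(alpha = 5, beta = 0, gamma = 0),
      F4 = c(alpha = 5 * sqrt(10), beta = 0, gamma = 0),
      FPz = c(alpha = 0, beta = 0, gamma = 0),
      Oz = c(alpha = 0, beta = 0, gamma = 0)),
    seed = 2)
  a3 <- band_power(rec2$values[, "F3"], 200, "alpha")
  a4 <- band_power(rec2$values[, "F4"], 200, "alpha")
  expect_lt(abs(faa(a4, a3) - 1.0), 1e-9)      # shared carrier: exact ratio

  # a 200 uV artifact at 10 s knocks out exactly the epochs overlapping it
  rec3 <- gen_synthetic_eeg(30, artifact_epochs = list(c(10, 200)), seed = 3)
  ep3 <- reject_amplitude(make_epochs(eeg_bandpass(rec3),
                                      channels = c("F3", "F4")))
  bad <- which(!ep3$retained)
  expect_true(length(bad) > 0)
  # overlapping epochs are those with onset in (10 - 2, 10.25]
  expect_true(all(ep3$onsets[bad] > 8 - 1e-9 & ep3$onsets[bad] <= 10.3))
  expect_true(all(ep3$retained[ep3$onsets > 10.3]))

  expect_error(gen_synthetic_eeg(10, rate = 80), "rate")
})

test_that("EEG pipeline recovers the planted FAA target over a seed batch", {
  got <- vapply(1:20, function(s) {
    rec <- gen_synthetic_eeg(60, faa_target = 0.4, seed = s)
    ep <- reject_amplitude(make_epochs(eeg_bandpass(rec),
                                       channels = c("F3", "F4")))
    mean(epoch_features(ep)$faa, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(got) - 0.4), 0.05)
})

test_that("gaze generator schedules blinks, dropouts and saccades as stated", {
  gz <- gen_gaze_trace(10, blink_schedule = list(c(2, 0.1), c(5, 0.1),
                                                 c(8, 0.1)),
                       saccades = list(c(3, 6)),
                       monocular_dropouts = list(c(6.5, 0.1, 1)), seed = 4)
  # blinks are simultaneous equal-length invalid runs in both eyes;
  # the monocular dropout is left-only
  expect_equal(sum(!gz$right$valid), 3 * 12)   # 0.1 s at 120 Hz = 12 samples
  expect_equal(sum(!gz$left$valid), 4 * 12)
  expect_true(all(which(!gz$right$valid) %in% which(!gz$left$valid)))
  L <- interpolate_gaps(velocity_filter(gz$left))
  R <- interpolate_gaps(velocity_filter(gz$right))
  bl <- detect_blinks(L, R)
  expect_equal(nrow(bl), 3)                    # monocular dropout adds none
  # the 6 degree step (720 deg/s at 120 Hz) was removed by the filter
  vf <- velocity_filter(gz$right)
  i <- floor(3 * 120) + 1
  expect_false(vf$valid[i])
  expect_error(gen_gaze_trace(10, blink_schedule = list(c(2, 0.1),
                                                        c(2.05, 0.1))),
               "overlap")
  # determinism
  g2 <- gen_gaze_trace(5, seed = 9)
  g3 <- gen_gaze_trace(5, seed = 9)
  expect_identical(g2$left$yaw, g3$left$yaw)
})

test_that("cohort generator is seeded, complete, and honors the design size", {
  co <- gen_cohort(2, layout = ride_layout(60), window_length = 8,
                   seed = 5, measures = "blink")
  expect_s3_class(co, "cohort")
  expect_length(co$subjects, 2)
  expect_named(co$subjects[[1]], c("Human", "SelfDriving"))
  res <- run_pipeline(co)
  a <- res$anova$blink
  # n = 2 minimal dataset: dfs (1, 1) and (2, 2)
  expect_equal(a$effects$df_num, c(1, 2, 2))
  expect_equal(a$effects$df_den, c(1, 2, 2))

  co2 <- gen_cohort(2, layout = ride_layout(60), window_length = 8,
                    seed = 5, measures = "blink")
  expect_identical(run_pipeline(co2)$measures, res$measures)
})

test_that("cohort round-trips through the CSV bundle format", {
  dir <- withr::local_tempdir()
  co <- gen_cohort(2, layout = ride_layout(40), window_length = 6,
                   seed = 6, noise_sd = 0.1)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "layout.json")))
  expect_true(file.exists(file.path(dir, "S01", "Human", "eeg.csv")))
  rt <- read_cohort(dir)
  expect_equal(rt$layout$total_duration, 40)
  expect_equal(rt$window_length, 6)
  b0 <- co$subjects$S01$Human
  b1 <- rt$subjects$S01$Human
  expect_equal(unname(b1$eeg$values[, "F3"]), unname(b0$eeg$values[, "F3"]),
               tolerance = 1e-6)
  expect_equal(b1$gaze$left$valid, b0$gaze$left$valid)
  expect_equal(b1$head$x_deg, b0$head$x_deg, tolerance = 1e-6)
})
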