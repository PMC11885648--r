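# Oculomotor rules: ellipse fit, angular conversion, velocity filter,
# gap interpolation, blink labeling, low-pass, blink counting.

test_that("ellipse fit recovers generating parameters within 2%", {
  cases <- list(list(c(10, 20), c(5, 3), 30),
                list(c(-4, 7), c(8, 2), 120),
                list(c(0, 0), c(1, 0.4), 175))
  for (cs in cases) {
    e <- fit_ellipse(ellipse_points(cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(e$center, cs[[1]], tolerance = 0.02)
    expect_equal(e$semi_axes, cs[[2]], tolerance = 0.02)
    expect_lt(min(abs(e$rotation - cs[[3]]),
                  180 - abs(e$rotation - cs[[3]])), 1)
  }
  # circle: rotation 0 by convention
  expect_equal(fit_ellipse(ellipse_points(c(1, 2), c(2, 2), 0))$rotation, 0)
  expect_error(fit_ellipse(ellipse_points(c(0, 0), c(2, 1), 0)[1:4, ]),
               "at least 5")
  expect_error(fit_ellipse(cbind(1:9, 2 * (1:9))))  # collinear
})

test_that("pixel coordinates map through the spherical bulbus model", {
  g <- eye_geometry(c(100, 100), 50)
  at_center <- pixels_to_degrees(100, 100, g)
  expect_equal(c(at_center$yaw, at_center$pitch), c(0, 0))
  d <- pixels_to_degrees(100 + 50 * sin(10 * pi / 180), 100, g)
  expect_equal(d$yaw, 10, tolerance = 1e-9)
  expect_equal(d$pitch, 0)
  out <- pixels_to_degrees(100 + 75, 100, g)   # 1.5 r off-center
  expect_false(out$valid)
  expect_true(is.na(out$yaw))
  # roll correction: a point along the rolled axis reads as pure yaw
  g45 <- eye_geometry(c(0, 0), 10, camera_roll = 45)
  p <- pixels_to_degrees(10 * sin(20 * pi / 180) * cos(pi / 4),
                         10 * sin(20 * pi / 180) * sin(pi / 4), g45)
  expect_equal(p$yaw, 20, tolerance = 1e-6)
  expect_equal(p$pitch, 0, tolerance = 1e-6)
})

test_that("velocity filter invalidates supra-threshold steps and is idempotent", {
  yaw <- rep(0, 120)
  yaw[61:120] <- 6                             # 6 deg step = 720 deg/s
  tr <- flat_trace(rep(TRUE, 120), yaw = yaw)
  vf <- velocity_filter(tr)
  expect_false(vf$valid[61])
  expect_true(all(vf$valid[-61]))              # later samples are static again
  expect_identical(velocity_filter(vf)$valid, vf$valid)

  yaw4 <- rep(0, 120); yaw4[61:120] <- 4       # 480 deg/s: kept
  expect_true(all(velocity_filter(flat_trace(rep(TRUE, 120),
                                             yaw = yaw4))$valid))
  # stationary trace unchanged
  st <- flat_trace(rep(TRUE, 50))
  expect_identical(velocity_filter(st), st)
})

test_that("gap interpolation fills <= 20 ms and flags longer runs", {
  # 2-sample gap between 1 and 4 degrees -> filled with 2, 3
  v <- rep(TRUE, 10); v[3:4] <- FALSE
  yaw <- c(0, 1, NA, NA, 4, 4, 4, 4, 4, 4)
  tr <- gaze_trace((0:9) / 120, yaw, rep(0, 10), v, 120)
  ip <- interpolate_gaps(tr)
  expect_equal(ip$yaw[3:4], c(2, 3))
  expect_true(all(ip$valid))
  expect_equal(nrow(ip$error_runs), 0)
  # idempotent
  expect_identical(interpolate_gaps(ip), ip)

  # 5-sample gap (41.7 ms) -> error run, not filled
  v2 <- rep(TRUE, 20); v2[6:10] <- FALSE
  tr2 <- flat_trace(v2)
  ip2 <- interpolate_gaps(tr2)
  expect_false(any(ip2$valid[6:10]))
  expect_equal(nrow(ip2$error_runs), 1)
  expect_equal(unname(ip2$error_runs[1, ]), c(5 / 120, 10 / 120),
               tolerance = 1e-9)

  # leading gap: error run regardless of length
  v3 <- rep(TRUE, 20); v3[1:2] <- FALSE
  ip3 <- interpolate_gaps(flat_trace(v3))
  expect_false(any(ip3$valid[1:2]))
  expect_equal(nrow(ip3$error_runs), 1)
})

test_that("blink labeling requires matching binocular error runs", {
  mk <- function(bad) {
    v <- rep(TRUE, 240); v[bad] <- FALSE
    interpolate_gaps(flat_trace(v))
  }
  blink1 <- 25:36                              # 100 ms
  blink2 <- 121:132
  L <- mk(c(blink1, blink2))
  R <- mk(c(blink1, blink2))
  expect_equal(nrow(detect_blinks(L, R)), 2)
  # left-only run: no blink
  expect_equal(nrow(detect_blinks(mk(blink1), mk(integer(0)))), 0)
  # one sample of slack is tolerated
  Rs <- mk(c(blink1 + 1, blink2))
  expect_equal(nrow(detect_blinks(L, Rs)), 2)
  # two samples is not
  R2 <- mk(c(blink1 + 2, blink2))
  expect_equal(nrow(detect_blinks(L, R2)), 1)
  # symmetric in eye order
  expect_equal(detect_blinks(L, Rs), detect_blinks(Rs, L))
  expect_error(detect_blinks(L, flat_trace(rep(TRUE, 100), rate = 60)),
               "rates")
})

test_that("low-pass preserves DC and the passband, guards Nyquist", {
  n <- 1200
  const <- gaze_trace((0:(n - 1)) / 240, rep(2, n), rep(-1, n),
                      rep(TRUE, n), 240)
  lp <- gaze_lowpass(const)                    # 60 Hz legal at 240 Hz
  expect_equal(lp$yaw, rep(2, n), tolerance = 1e-9)
  s5 <- sin(2 * pi * 5 * (0:(n - 1)) / 240)
  tr5 <- gaze_trace((0:(n - 1)) / 240, s5, rep(0, n), rep(TRUE, n), 240)
  expect_equal(max(abs(gaze_lowpass(tr5)$yaw[300:900])), 1, tolerance = 0.05)
  # 60 Hz cutoff at 120 Hz rate: warning + 50 Hz fallback by default,
  # error when the cutoff was explicit
  tr120 <- flat_trace(rep(TRUE, 240))
  expect_warning(gaze_lowpass(tr120), "Nyquist")
  expect_error(gaze_lowpass(tr120, cutoff = 60, explicit_cutoff = TRUE),
               "Nyquist")
})

test_that("blink counts per segment assign by start time", {
  segs <- event_windows(ride_layout(180), 20)
  b <- structure(cbind(start = c(86, 90, 100), end = c(86.2, 90.2, 100.2)),
                 class = "blink_events")
  bf <- blink_frequency(b, segs)
  expect_equal(bf$blinks, c(0L, 3L, 0L))
  # straddling blink counted once, by start
  b2 <- structure(cbind(start = 104.9, end = 105.4), class = "blink_events")
  expect_equal(blink_frequency(b2, segs)$blinks, c(0L, 1L, 0L))
  none <- structure(matrix(numeric(0), ncol = 2), class = "blink_events")
  expect_equal(blink_frequency(none, segs)$blinks, c(0L, 0L, 0L))
})

test_that("a planted supra-threshold saccade never survives cleaning", {
  withr::with_seed(8, for (i in 1:5) {
    on <- runif(1, 1, 8)
    gz <- gen_gaze_trace(10, saccades = list(c(on, runif(1, 5, 30))),
                         seed = i)
    cl <- clean_gaze(gz$left)
    ok <- which(cl$valid)
    step <- sqrt(diff(cl$yaw[ok])^2 + diff(cl$pitch[ok])^2)
    expect_true(all(step / diff(cl$time[ok]) <= 500))
  })
})
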