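# Shared fixture builders (everything is generated in code; no files).

# four-channel recording where every channel is the same signal
tone_recording <- function(freq, rate = 200, duration = 10, amplitude = 1) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  x <- amplitude * sin(2 * pi * freq * t)
  recording(cbind(F3 = x, F4 = x, FPz = x, Oz = x), rate = rate)
}

# balanced 2 x 3 within-subject cell table with iid N(0,1) values
random_cell_table <- function(n, seed = NULL) {
  tb <- expand.grid(subject = sprintf("s%02d", seq_len(n)),
                    condition = c("Human", "SelfDriving"),
                    event = c("Smooth", "Deer", "Kid"),
                    stringsAsFactors = FALSE)
  tb$value <- if (is.null(seed)) stats::rnorm(nrow(tb))
  else withr::with_seed(seed, stats::rnorm(nrow(tb)))
  tb
}

# points on an ellipse boundary
ellipse_points <- function(center, axes, rotation_deg, n = 40) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rotation_deg * pi / 180
  cbind(center[1] + axes[1] * cos(th) * cos(r) - axes[2] * sin(th) * sin(r),
        center[2] + axes[1] * cos(th) * sin(r) + axes[2] * sin(th) * cos(r))
}

# gaze trace with explicit validity vector, constant-rate time base
flat_trace <- function(valid, rate = 120, yaw = NULL) {
  n <- length(valid)
  if (is.null(yaw)) yaw <- rep(0, n)
  pitch <- rep(0, n)
  yaw[!valid] <- NA
  pitch[!valid] <- NA
  gaze_trace((seq_len(n) - 1) / rate, yaw, pitch, valid, rate)
}
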