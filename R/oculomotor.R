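# Oculomotor processing: ellipse fit of the segmented pupil, pixel-to-
# degree conversion on a spherical eyeball model, the 500 deg/s velocity
# rule, 20 ms gap interpolation, binocular blink labeling, final low-pass,
# and per-segment blink counting.

#' Eye geometry for pixel-to-degree conversion
#'
#' @param bulbus_center c(x, y) center of the vitreous body in pixels.
#' @param bulbus_radius radius of the bulbus oculi in pixels.
#' @param camera_roll camera roll in degrees (angle of the line through
#'   the medial/lateral rectus landmarks).
#' @return object of class `eye_geometry`.
#' @export
eye_geometry <- function(bulbus_center, bulbus_radius, camera_roll = 0) {
  stopifnot(length(bulbus_center) == 2, bulbus_radius > 0)
  structure(list(center = as.numeric(bulbus_center),
                 radius = bulbus_radius, roll = camera_roll),
            class = "eye_geometry")
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic ax^2 + bxy + cy^2 + dx + ey + f = 0 to boundary points
#' with the ellipse constraint 4ac - b^2 = 1 (Fitzgibbon's direct method
#' in the numerically stable partitioned form), then converts to center,
#' semi-axes and rotation. A circle reports rotation 0 by convention.
#'
#' @param points two-column matrix or data.frame of (x, y) boundary points
#'   (at least 5, not collinear).
#' @return object of class `ellipse_params`: list with `center`,
#'   `semi_axes` (a >= b) and `rotation` in degrees in \[0, 180).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5) stop("need at least 5 boundary points")
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)                 # center for conditioning
  xs <- x - mx; ys <- y - my
  d1 <- cbind(xs^2, xs * ys, ys^2)
  d2 <- cbind(xs, ys, 1)
  s1 <- crossprod(d1); s2 <- crossprod(d1, d2); s3 <- crossprod(d2)
  t_ <- tryCatch(-solve(s3, t(s2)), error = function(e)
    stop("degenerate point set: ellipse fit failed"))
  m <- s1 + s2 %*% t_
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("degenerate point set: no ellipse solution")
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.numeric(t_ %*% a1))         # a b c d e f (centered)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F_ <- coef[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("fit did not yield an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F_
  qm <- matrix(c(A, B / 2, B / 2, C), 2)
  eg <- eigen(qm, symmetric = TRUE)
  axes <- sqrt(-Fc / eg$values)                # semi-axis per eigenvector
  if (any(!is.finite(axes))) stop("fit did not yield an ellipse")
  semi <- sort(axes, decreasing = TRUE)
  if (abs(semi[1] - semi[2]) < 1e-9 * semi[1]) {
    rot <- 0                                   # circle: rotation convention
  } else {
    vmaj <- eg$vectors[, which.max(axes)]      # major-axis direction
    rot <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180
  }
  structure(list(center = c(cx + mx, cy + my), semi_axes = semi,
                 rotation = rot),
            class = "ellipse_params")
}

#' Convert pupil-center pixels to degrees of rotation
#'
#' Roll-corrects the pixel offset from the bulbus center and maps it
#' through a spherical eyeball model: yaw = asin(dx / r),
#' pitch = asin(dy / r), both in degrees. Points outside the bulbus disk
#' are marked invalid.
#'
#' @param x,y pupil-center pixel coordinates (vectors).
#' @param geometry an [eye_geometry()].
#' @return data.frame: yaw, pitch (degrees; NA when invalid), valid.
#' @export
pixels_to_degrees <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "eye_geometry"))
  dx <- x - geometry$center[1]
  dy <- y - geometry$center[2]
  th <- -geometry$roll * pi / 180
  rx <- dx * cos(th) - dy * sin(th)
  ry <- dx * sin(th) + dy * cos(th)
  r <- geometry$radius
  valid <- is.finite(rx) & is.finite(ry) & (rx^2 + ry^2) <= r^2
  yaw <- ifelse(valid, asin(pmin(1, pmax(-1, rx / r))) * 180 / pi, NA_real_)
  pitch <- ifelse(valid, asin(pmin(1, pmax(-1, ry / r))) * 180 / pi, NA_real_)
  data.frame(yaw = yaw, pitch = pitch, valid = valid)
}

#' Angular velocity filter
#'
#' Invalidates the later sample of every consecutive valid pair whose
#' total angular step sqrt(dyaw^2 + dpitch^2) times the implied rate
#' exceeds `vmax` degrees per second, repeating until no violation
#' remains (so the result is a fixed point and the operation idempotent).
#'
#' @param trace a [gaze_trace()].
#' @param vmax velocity bound in deg/s (default 500).
#' @return the filtered `gaze_trace`.
#' @export
velocity_filter <- function(trace, vmax = 500) {
  stopifnot(inherits(trace, "gaze_trace"))
  repeat {
    idx <- which(trace$valid)
    if (length(idx) < 2) break
    dt <- diff(trace$time[idx])
    step <- sqrt(diff(trace$yaw[idx])^2 + diff(trace$pitch[idx])^2)
    bad <- which(step / dt > vmax)
    if (length(bad) == 0) break
    kill <- idx[bad + 1]
    trace$valid[kill] <- FALSE
    trace$yaw[kill] <- NA
    trace$pitch[kill] <- NA
  }
  trace
}

#' Fill short gaps, flag long ones as measurement errors
#'
#' Invalid runs lasting at most `max_gap` seconds (about 2 frames at
#' 120 Hz) are filled by linear interpolation between the flanking valid
#' samples and marked valid. Longer runs — and any run touching the edge
#' of the series, which has no flanking sample — are recorded in
#' `error_runs` and left invalid.
#'
#' @param trace a [gaze_trace()].
#' @param max_gap longest fillable gap in seconds (default 0.020).
#' @return the `gaze_trace` with gaps filled and `error_runs` updated.
#' @export
interpolate_gaps <- function(trace, max_gap = 0.020) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- length(trace$time)
  runs <- runs_of(!trace$valid)
  period <- 1 / trace$rate
  err <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    dur <- (b - a + 1) * period
    edge <- a == 1 || b == n
    if (!edge && dur <= max_gap + 1e-12) {
      w <- (seq(a, b) - (a - 1)) / (b - a + 2)
      trace$yaw[a:b] <- trace$yaw[a - 1] +
        w * (trace$yaw[b + 1] - trace$yaw[a - 1])
      trace$pitch[a:b] <- trace$pitch[a - 1] +
        w * (trace$pitch[b + 1] - trace$pitch[a - 1])
      trace$valid[a:b] <- TRUE
    } else {
      err[[length(err) + 1]] <- c(trace$time[a], trace$time[b] + period)
    }
  }
  if (length(err)) {
    new_runs <- do.call(rbind, err)
    colnames(new_runs) <- c("start", "end")
    all_runs <- rbind(trace$error_runs, new_runs)
    all_runs <- all_runs[!duplicated(round(all_runs, 9)), , drop = FALSE]
    trace$error_runs <- all_runs[order(all_runs[, 1]), , drop = FALSE]
  }
  trace
}

#' Label binocular measurement errors as blinks
#'
#' An error run counts as a blink when both eyes show one with matching
#' extent: start and end agree within one sample period (exact sample
#' equality would be fragile under independent per-eye processing). The
#' result is symmetric in eye order; each run is matched at most once.
#'
#' @param left,right [gaze_trace()] objects on a common time base.
#' @return object of class `blink_events`: matrix of \[start, end)
#'   second intervals.
#' @export
detect_blinks <- function(left, right) {
  stopifnot(inherits(left, "gaze_trace"), inherits(right, "gaze_trace"))
  if (left$rate != right$rate) stop("eyes sampled at different rates")
  tol <- 1 / left$rate + 1e-9
  lr <- left$error_runs; rr <- right$error_runs
  used <- rep(FALSE, nrow(rr))
  out <- list()
  for (i in seq_len(nrow(lr))) {
    for (j in seq_len(nrow(rr))) {
      if (used[j]) next
      if (abs(lr[i, 1] - rr[j, 1]) <= tol &&
          abs(lr[i, 2] - rr[j, 2]) <= tol) {
        out[[length(out) + 1]] <- c(min(lr[i, 1], rr[j, 1]),
                                    max(lr[i, 2], rr[j, 2]))
        used[j] <- TRUE
        break
      }
    }
  }
  m <- if (length(out)) do.call(rbind, out)
  else matrix(numeric(0), ncol = 2)
  colnames(m) <- c("start", "end")
  structure(m[order(m[, 1]), , drop = FALSE], class = "blink_events")
}

#' Final low-pass of a gaze trace
#'
#' Second-order zero-phase Butterworth low-pass, nominally 60 Hz to
#' suppress sampling-frequency harmonics. At the 120 Hz eye-camera rate a
#' 60 Hz cutoff sits exactly at Nyquist; in that case the default falls
#' back to 50 Hz with a warning, and an explicitly requested cutoff at or
#' above Nyquist is an error. Remaining invalid samples are interpolated
#' for filtering and re-masked afterwards.
#'
#' @param trace a [gaze_trace()].
#' @param cutoff cutoff frequency in Hz (default 60, see above).
#' @param order one-way filter order (default 2).
#' @param explicit_cutoff set TRUE when `cutoff` was user-chosen, making a
#'   Nyquist violation an error instead of a fallback.
#' @return the filtered `gaze_trace`.
#' @export
gaze_lowpass <- function(trace, cutoff = 60, order = 2,
                         explicit_cutoff = FALSE) {
  stopifnot(inherits(trace, "gaze_trace"))
  nyq <- trace$rate / 2
  if (cutoff >= nyq) {
    if (explicit_cutoff)
      stop(sprintf(
        "cutoff %g Hz is at/above Nyquist (%g Hz); choose a lower cutoff",
        cutoff, nyq))
    warning(sprintf(
      "cutoff %g Hz at/above Nyquist (%g Hz); falling back to 50 Hz",
      cutoff, nyq))
    cutoff <- min(50, 0.9 * nyq)
  }
  fill <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(!is.na(v))
    if (length(ok) < 2) return(v)
    stats::approx(trace$time[ok], v[ok], xout = trace$time, rule = 2)$y
  }
  yaw <- filter_zerophase(fill(trace$yaw), trace$rate, order, high = cutoff)
  pitch <- filter_zerophase(fill(trace$pitch), trace$rate, order,
                            high = cutoff)
  yaw[!trace$valid] <- NA
  pitch[!trace$valid] <- NA
  trace$yaw <- yaw
  trace$pitch <- pitch
  trace
}

#' Blink counts per segment
#'
#' Each blink is assigned to the segment containing its start time; a
#' blink straddling a boundary is counted once.
#'
#' @param blinks a `blink_events` object (or 2-column start/end matrix).
#' @param segments data.frame with `start`, `end` and a label column
#'   (e.g. from [event_windows()]).
#' @return `segments` with an added integer `blinks` column.
#' @export
blink_frequency <- function(blinks, segments) {
  b <- unclass(blinks)
  out <- segments
  out$blinks <- vapply(seq_len(nrow(segments)), function(i)
    sum(b[, 1] >= segments$start[i] & b[, 1] < segments$end[i]),
    integer(1))
  out
}

#' Full monocular cleaning chain
#'
#' velocity filter -> gap interpolation -> (blink detection happens across
#' eyes, separately) -> low-pass. Convenience wrapper used by the
#' pipeline.
#'
#' @param trace a [gaze_trace()].
#' @param vmax velocity bound (deg/s).
#' @param max_gap longest fillable gap (s).
#' @param cutoff low-pass cutoff (Hz); the Nyquist fallback applies.
#' @return cleaned `gaze_trace`.
#' @export
clean_gaze <- function(trace, vmax = 500, max_gap = 0.020, cutoff = 60) {
  # Iterate to a fixed point: interpolating across an invalidated saccade
  # sample can itself create a supra-threshold step (half the original),
  # which the next velocity pass removes; steps shrink geometrically so
  # this converges in a few rounds.
  for (i in 1:10) {
    t1 <- velocity_filter(trace, vmax = vmax)
    t1 <- interpolate_gaps(t1, max_gap = max_gap)
    done <- identical(t1$yaw, trace$yaw) && identical(t1$valid, trace$valid)
    trace <- t1
    if (done) break
  }
  suppressWarnings(gaze_lowpass(trace, cutoff = cutoff))
}
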