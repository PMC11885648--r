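# Synthetic inputs with known ground truth: binomial cascades and
# fractional Gaussian noise as multifractal/monofractal fixtures,
# band-structured EEG with a controllable frontal alpha-power ratio,
# binocular gaze traces with scheduled blinks/saccades/dropouts, and a
# whole cohort with planted Condition and Route-event effects.

#' Multichannel recording container
#'
#' @param values numeric matrix, samples in rows, channels in columns.
#' @param rate sampling rate in Hz.
#' @param channel_names unique channel labels (default from colnames).
#' @param t0 time of the first sample in seconds.
#' @param units signal units (default microvolts).
#' @return object of class `recording`.
#' @export
recording <- function(values, rate, channel_names = colnames(values),
                      t0 = 0, units = "uV") {
  values <- as.matrix(values)
  if (is.null(channel_names) || anyDuplicated(channel_names))
    stop("recording needs unique channel names")
  colnames(values) <- channel_names
  structure(list(values = values, rate = rate,
                 channel_names = channel_names, t0 = t0, units = units),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d samples x %d channels (%s) at %g Hz, %.1f s\n",
              nrow(x$values), ncol(x$values),
              paste(x$channel_names, collapse = ", "), x$rate,
              nrow(x$values) / x$rate))
  invisible(x)
}

rec_time <- function(rec) rec$t0 + (seq_len(nrow(rec$values)) - 1) / rec$rate

#' Binomial multiplicative cascade measure
#'
#' Builds the deterministic two-scale cascade: mass 1 on a dyadic grid is
#' split recursively in proportions p and 1-p through `depth` refinements,
#' giving 2^depth cells that sum to 1. Its singularity spectrum is known in
#' closed form ([binomial_spectrum_theory()]), making it the oracle for the
#' Chhabra-Jensen estimator. With `randomize = TRUE` the left/right
#' assignment of p is drawn per split (a random cascade with the same
#' spectrum).
#'
#' @param p multiplier weight in (0, 1).
#' @param depth number of dyadic refinements (1..24; deeper is refused as a
#'   memory guard).
#' @param randomize randomize multiplier orientation per split.
#' @param seed RNG seed, used only when `randomize = TRUE`.
#' @return numeric vector of 2^depth cell masses summing to 1.
#' @export
gen_binomial_cascade <- function(p, depth, randomize = FALSE, seed = NULL) {
  stopifnot(p > 0, p < 1, depth >= 1)
  if (depth > 24) stop("depth > 24 refused (2^depth cells would be huge)")
  with_seed_(if (randomize) seed else NULL, {
    m <- 1
    for (i in seq_len(depth)) {
      k <- length(m)
      flip <- if (randomize) stats::runif(k) < 0.5 else rep(FALSE, k)
      a <- ifelse(flip, 1 - p, p)
      m <- as.vector(rbind(m * a, m * (1 - a)))
    }
    m
  })
}

#' Cascade-modulated Gaussian series
#'
#' Turns a cascade measure into a displacement-like time series: cell
#' masses act as local variances of white Gaussian noise, and positions are
#' the running sum of those increments. The absolute first differences of
#' the result recover (noisy) cascade weights, which is exactly what the
#' time-series route of [chhabra_jensen()] measures.
#'
#' @param p,depth,seed as in [gen_binomial_cascade()]; `seed` drives the
#'   Gaussian noise.
#' @param n optional output length (truncates the 2^depth series).
#' @param sd overall scale of the increments.
#' @param cumulative return positions (cumsum of increments, default) or
#'   the increments themselves.
#' @return numeric series of length `n` (default 2^depth).
#' @export
cascade_series <- function(p, depth, seed = NULL, n = NULL, sd = 1,
                           cumulative = TRUE) {
  m <- gen_binomial_cascade(p, depth)
  inc <- with_seed_(seed, stats::rnorm(length(m), sd = sqrt(m * length(m)))) * sd
  if (!is.null(n)) {
    stopifnot(n <= length(inc))
    inc <- inc[seq_len(n)]
  }
  if (cumulative) cumsum(inc) else inc
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation (Davies-Harte): the fGn autocovariance
#' \eqn{\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' is embedded in a circulant matrix whose eigenvalues, obtained by FFT,
#' are nonnegative for all H in (0, 1); coloring complex white noise by
#' their square roots yields a series with exactly this autocovariance.
#'
#' @param hurst Hurst exponent in (0, 1). H = 0.5 gives white noise.
#' @param n series length (positive).
#' @param seed RNG seed.
#' @param sd marginal standard deviation (default 1).
#' @return numeric vector of length n, zero-mean Gaussian.
#' @export
gen_fgn <- function(hurst, n, seed = NULL, sd = 1) {
  stopifnot(hurst > 0, hurst < 1, n >= 1)
  h2 <- 2 * hurst
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  m <- 2L * n
  circ <- c(g[1:n], g[n + 1], g[n:2])[1:m]     # gamma(0..n, n-1..1)
  lam <- Re(stats::fft(circ))
  lam[lam < 0 & lam > -1e-8] <- 0              # clip tiny negative rounding
  if (any(lam < 0)) stop("circulant embedding not nonnegative definite")
  with_seed_(seed, {
    # coloring independent complex white noise by sqrt(lam/m) makes the
    # real part of the FFT a Gaussian series with autocovariance gamma
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    x <- Re(stats::fft(sqrt(lam / m) * z))[1:n]
    x * sd
  })
}

eeg_band_table <- function() {
  list(alpha = c(8, 12), beta = c(13, 30), gamma = c(30, 45))
}

# unit-RMS band-limited noise carrier (brick-wall FFT band-pass of white noise)
band_carrier <- function(n, rate, band) {
  x <- stats::rnorm(n)
  freqs <- seq_len(n) - 1
  freqs <- pmin(freqs, n - freqs) * rate / n
  keep <- freqs >= band[1] & freqs <= band[2]
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthetic band-structured EEG
#'
#' Each channel is a sum of shared band-limited noise carriers (alpha
#' 8-12, beta 13-30, gamma 30-45 Hz) scaled by per-channel amplitudes,
#' plus optional square-pulse artifacts. Because F3 and F4 share the same
#' alpha carrier, the realized F4/F3 alpha power ratio equals the amplitude
#' ratio exactly, so a requested frontal-asymmetry target is planted
#' without estimation error. Band power of a channel in a band is
#' (amplitude)^2 since carriers have unit RMS.
#'
#' @param duration seconds.
#' @param rate sampling rate in Hz (default 200; must exceed 96 Hz so the
#'   gamma band is representable).
#' @param band_amplitudes named list channel -> named numeric
#'   c(alpha=, beta=, gamma=) in microvolts RMS. Channels default to
#'   F3, F4, FPz, Oz with amplitudes alpha 10, beta 5, gamma 2.
#' @param faa_target if non-NULL, the F4 alpha amplitude is set to
#'   `10^(faa_target/2)` times the F3 alpha amplitude so the downstream
#'   frontal alpha asymmetry equals `faa_target`.
#' @param faa_profile optional data.frame (start, end, faa) of per-interval
#'   targets; overrides `faa_target` piecewise in time.
#' @param artifact_epochs list of c(onset_s, amplitude_uV): a 0.25 s
#'   in-band (12.5 Hz square-wave) deflection added to every channel at
#'   each onset, emulating a movement artifact that survives band-pass
#'   filtering.
#' @param seed RNG seed.
#' @return a [recording()].
#' @export
gen_synthetic_eeg <- function(duration, rate = 200, band_amplitudes = NULL,
                              faa_target = NULL, faa_profile = NULL,
                              artifact_epochs = NULL, seed = NULL) {
  stopifnot(duration > 0, rate > 96)
  bands <- eeg_band_table()
  if (max(vapply(bands, max, 0)) >= rate / 2)
    stop("sampling rate too low for the gamma band")
  chans <- c("F3", "F4", "FPz", "Oz")
  amp_default <- c(alpha = 10, beta = 5, gamma = 2)
  amps <- lapply(chans, function(ch) {
    a <- amp_default
    if (!is.null(band_amplitudes[[ch]])) {
      got <- band_amplitudes[[ch]]
      a[names(got)] <- got
    }
    if (any(a < 0)) stop("band amplitudes must be nonnegative")
    a
  })
  names(amps) <- chans
  if (!is.null(faa_target) && is.null(faa_profile))
    amps$F4["alpha"] <- amps$F3["alpha"] * 10^(faa_target / 2)

  n <- round(duration * rate)
  with_seed_(seed, {
    carriers <- lapply(bands, function(b) band_carrier(n, rate, b))
    vals <- vapply(chans, function(ch) {
      amps[[ch]]["alpha"] * carriers$alpha +
        amps[[ch]]["beta"] * carriers$beta +
        amps[[ch]]["gamma"] * carriers$gamma
    }, numeric(n))
    if (!is.null(faa_profile)) {                # piecewise F4 alpha gain
      tt <- (seq_len(n) - 1) / rate
      gain <- rep(1, n)
      for (i in seq_len(nrow(faa_profile))) {
        hit <- tt >= faa_profile$start[i] & tt < faa_profile$end[i]
        gain[hit] <- 10^(faa_profile$faa[i] / 2)
      }
      vals[, "F4"] <- vals[, "F4"] +
        amps$F3["alpha"] * (gain - 1) * carriers$alpha
    }
    for (a in artifact_epochs) {
      i0 <- round(a[1] * rate) + 1
      i1 <- min(n, i0 + round(0.25 * rate))
      if (i0 <= n) {
        # in-band (12.5 Hz square) burst so the deflection survives the
        # 7-48 Hz band-pass and trips the amplitude rejection downstream
        burst <- a[2] * sign(sin(2 * pi * 12.5 *
                                   (seq(i0, i1) - i0) / rate))
        vals[i0:i1, ] <- vals[i0:i1, ] + burst
      }
    }
    recording(vals, rate = rate, channel_names = chans)
  })
}

#' Gaze trace container
#'
#' @param time sample times in seconds.
#' @param yaw,pitch angular position in degrees (NA where invalid).
#' @param valid logical validity per sample.
#' @param rate sampling rate in Hz.
#' @param error_runs matrix of \[start, end) second intervals flagged as
#'   measurement errors (gaps longer than the interpolation limit).
#' @return object of class `gaze_trace`.
#' @export
gaze_trace <- function(time, yaw, pitch, valid = rep(TRUE, length(time)),
                       rate, error_runs = NULL) {
  stopifnot(length(time) == length(yaw), length(yaw) == length(pitch),
            length(valid) == length(time))
  if (is.null(error_runs))
    error_runs <- matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  structure(list(time = time, yaw = yaw, pitch = pitch,
                 valid = as.logical(valid), rate = rate,
                 error_runs = error_runs),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("gaze_trace: %d samples at %g Hz, %d invalid, %d error runs\n",
              length(x$time), x$rate, sum(!x$valid), nrow(x$error_runs)))
  invisible(x)
}

#' Synthetic binocular gaze traces
#'
#' Fixation jitter (a small random walk in yaw/pitch) with scheduled
#' events: `blink_schedule` produces simultaneous equal-length invalid runs
#' in both eyes; `monocular_dropouts` invalidate one eye only; `saccades`
#' add instantaneous angular steps (which downstream velocity filtering
#' must catch when step x rate exceeds 500 deg/s). Scheduled events must
#' not overlap.
#'
#' @param duration seconds.
#' @param rate sampling rate in Hz (default 120).
#' @param blink_schedule list of c(onset_s, duration_s).
#' @param saccades list of c(onset_s, step_deg) applied to both eyes.
#' @param monocular_dropouts list of c(onset_s, duration_s, eye) with eye
#'   1 = left, 2 = right.
#' @param jitter_sd per-sample random-walk step SD in degrees.
#' @param seed RNG seed.
#' @return list with `left` and `right` [gaze_trace()] objects.
#' @export
gen_gaze_trace <- function(duration, rate = 120, blink_schedule = list(),
                           saccades = list(), monocular_dropouts = list(),
                           jitter_sd = 0.02, seed = NULL) {
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  iv <- function(on, dur) {
    i0 <- floor(on * rate) + 1
    i1 <- min(n, i0 + max(1, round(dur * rate)) - 1)
    i0:i1
  }
  occupied <- lapply(c(blink_schedule, monocular_dropouts),
                     function(e) iv(e[1], e[2]))
  if (length(occupied) > 1) {
    all_idx <- unlist(occupied)
    if (anyDuplicated(all_idx) > 0) stop("scheduled events overlap")
  }
  with_seed_(seed, {
    mk_eye <- function() {
      yaw <- cumsum(stats::rnorm(n, sd = jitter_sd))
      pitch <- cumsum(stats::rnorm(n, sd = jitter_sd))
      for (s in saccades) {
        i0 <- floor(s[1] * rate) + 1
        if (i0 <= n) yaw[i0:n] <- yaw[i0:n] + s[2]
      }
      list(yaw = yaw, pitch = pitch, valid = rep(TRUE, n))
    }
    left <- mk_eye(); right <- mk_eye()
    for (b in blink_schedule) {
      i <- iv(b[1], b[2])
      left$valid[i] <- FALSE; right$valid[i] <- FALSE
    }
    for (d in monocular_dropouts) {
      i <- iv(d[1], d[2])
      if (d[3] == 1) left$valid[i] <- FALSE else right$valid[i] <- FALSE
    }
    finish <- function(e) {
      e$yaw[!e$valid] <- NA; e$pitch[!e$valid] <- NA
      gaze_trace(tt, e$yaw, e$pitch, e$valid, rate)
    }
    list(left = finish(left), right = finish(right))
  })
}

# invert the closed-form cascade width on the q grid: width -> multiplier p
width_to_p <- function(width, q = seq(-5, 5, 0.25)) {
  w_of_p <- function(p) {
    th <- binomial_spectrum_theory(p, q)
    max(th$alpha) - min(th$alpha)
  }
  stopifnot(width > 0, width < w_of_p(0.02))
  stats::uniroot(function(p) w_of_p(p) - width,
                 c(0.02, 0.4999), tol = 1e-8)$root
}

#' Synthetic cohort with planted effects
#'
#' Generates per-subject, per-condition bundles — EEG, binocular gaze,
#' head displacement and a route layout — realizing a 2 (Condition:
#' Human / SelfDriving) x 3 (Route event: Smooth / Deer / Kid) design with
#' per-subject random intercepts:
#' \itemize{
#'   \item Frontal alpha asymmetry: per-cell target = subject intercept
#'     +/- `condition_effect_faa`/2 (Human positive) + N(0, `noise_sd`),
#'     planted via the F4/F3 alpha amplitude ratio, piecewise over the
#'     four EEG segments.
#'   \item Multifractal width: displacement traces are cascade-modulated
#'     noise; the deer window's cascade multiplier is chosen so its
#'     closed-form width exceeds the baseline width by
#'     `event_effect_mfsw` (the deer encounter is the surprising event;
#'     the kid window stays at baseline).
#'   \item Blinks: a Poisson schedule at `blink_rate`, multiplied by
#'     `event_effect_blink` inside the deer and kid windows.
#' }
#'
#' @param n_subjects number of subjects (>= 2).
#' @param layout a [ride_layout()] (default 180 s, events at 50% and 90%).
#' @param condition_effect_faa planted Human-minus-SelfDriving FAA
#'   difference.
#' @param event_effect_mfsw planted deer-minus-smooth spectrum-width
#'   difference (on the closed-form cascade scale).
#' @param event_effect_blink blink-rate multiplier inside event windows.
#' @param noise_sd within-cell SD of the planted FAA values.
#' @param window_length event-window length in seconds (default 20).
#' @param base_width baseline cascade spectrum width (default 0.5).
#' @param blink_rate baseline blink rate in Hz (default 0.25, i.e.
#'   15 blinks/min).
#' @param measures which raw streams to generate: any of "eeg", "gaze",
#'   "head", "blink" (default all; trimming speeds up simulations).
#' @param seed RNG seed (required for reproducibility).
#' @return object of class `cohort`: list with `subjects` (nested
#'   per-subject, per-condition bundles), `layout`, `window_length`,
#'   `truth` (planted parameters).
#' @export
gen_cohort <- function(n_subjects, layout = ride_layout(180),
                       condition_effect_faa = 0, event_effect_mfsw = 0,
                       event_effect_blink = 1, noise_sd = 0.1,
                       window_length = 20, base_width = 0.5,
                       blink_rate = 0.25,
                       measures = c("eeg", "gaze", "head", "blink"),
                       seed = NULL) {
  stopifnot(n_subjects >= 2, noise_sd >= 0, event_effect_blink >= 0)
  measures <- match.arg(measures, several.ok = TRUE)
  segs <- eeg_segments(layout)
  wins <- event_windows(layout, window_length)
  qgrid <- mf_config()$q
  p_base <- width_to_p(base_width, qgrid)
  p_deer <- width_to_p(base_width + event_effect_mfsw, qgrid)

  with_seed_(seed, {
    subj_int_faa <- stats::rnorm(n_subjects, sd = 0.1)
    subj_blink <- exp(stats::rnorm(n_subjects, sd = 0.2))
    subjects <- lapply(seq_len(n_subjects), function(s) {
      conds <- lapply(c(Human = "Human", SelfDriving = "SelfDriving"),
                      function(cond) {
        csign <- if (cond == "Human") 0.5 else -0.5
        faa_cells <- subj_int_faa[s] + csign * condition_effect_faa +
          stats::rnorm(3, sd = noise_sd)          # Smooth, Deer, Kid
        names(faa_cells) <- c("Smooth", "Deer", "Kid")
        bundle <- list(faa_cells = faa_cells)
        if ("eeg" %in% measures) {
          prof <- data.frame(
            start = segs$start, end = segs$end,
            faa = faa_cells[c("Smooth", "Deer", "Smooth", "Kid")])
          bundle$eeg <- gen_synthetic_eeg(
            duration = layout$total_duration, rate = 200,
            faa_profile = prof,
            seed = sample.int(2^31 - 1, 1))
        }
        if ("gaze" %in% measures || "head" %in% measures) {
          # Each analysis window gets its own cascade, aligned to the
          # window start (a slice cut mid-cascade would inherit coarse-
          # scale mass imbalance and bias its width upward); filler
          # between windows is plain jitter.
          mk_disp <- function(rate) {
            n <- round(layout$total_duration * rate)
            x <- cumsum(stats::rnorm(n, sd = 0.05))
            for (ev in c("smooth", "deer", "kid")) {
              i <- which(tt_in(n, rate, wins[wins$event == ev, ]))
              if (length(i) < 2) next
              p_ev <- if (ev == "deer") p_deer else p_base
              seg <- cascade_series(p_ev, ceiling(log2(length(i))),
                                    seed = sample.int(2^31 - 1, 1),
                                    n = length(i), sd = 0.05)
              x[i] <- x[i[1]] + seg - seg[1]
              if (max(i) < n)                     # rejoin tail continuously
                x[(max(i) + 1):n] <- x[(max(i) + 1):n] -
                  x[max(i) + 1] + x[max(i)]
            }
            x
          }
          if ("gaze" %in% measures) {
            gz <- lapply(c("left", "right"), function(eye) {
              rate <- 120
              n <- round(layout$total_duration * rate)
              gaze_trace((seq_len(n) - 1) / rate,
                         yaw = mk_disp(rate), pitch = mk_disp(rate),
                         rate = rate)
            })
            names(gz) <- c("left", "right")
            bundle$gaze <- gz
          }
          if ("head" %in% measures)
            bundle$head <- list(rate = 30, x_deg = mk_disp(30),
                                y_deg = mk_disp(30))
        }
        if ("blink" %in% measures) {
          rate_fun <- function(t) {
            r <- rep(blink_rate * subj_blink[s], length(t))
            for (ev in c("deer", "kid")) {
              wv <- wins[wins$event == ev, ]
              r[t >= wv$start & t < wv$end] <-
                blink_rate * subj_blink[s] * event_effect_blink
            }
            r
          }
          tgrid <- seq(0, layout$total_duration - 0.3, by = 0.1)
          lam <- rate_fun(tgrid) * 0.1
          hit <- stats::runif(length(tgrid)) < lam
          bundle$blinks <- cbind(start = tgrid[hit],
                                 end = tgrid[hit] + 0.15)
          if (!is.null(bundle$gaze)) {   # blinks -> binocular invalid runs
            for (eye in c("left", "right")) {
              g <- bundle$gaze[[eye]]
              for (i in seq_len(nrow(bundle$blinks))) {
                hit_i <- g$time >= bundle$blinks[i, "start"] &
                  g$time < bundle$blinks[i, "end"]
                g$valid[hit_i] <- FALSE
                g$yaw[hit_i] <- NA
                g$pitch[hit_i] <- NA
              }
              bundle$gaze[[eye]] <- g
            }
          }
        }
        bundle
      })
      conds
    })
    names(subjects) <- sprintf("S%02d", seq_len(n_subjects))
    structure(list(subjects = subjects, layout = layout,
                   window_length = window_length,
                   truth = list(condition_effect_faa = condition_effect_faa,
                                event_effect_mfsw = event_effect_mfsw,
                                event_effect_blink = event_effect_blink,
                                noise_sd = noise_sd,
                                base_width = base_width,
                                p_base = p_base, p_deer = p_deer,
                                subj_int_faa = subj_int_faa)),
              class = "cohort")
  })
}

tt_in <- function(n, rate, win) {
  tt <- (seq_len(n) - 1) / rate
  tt >= win$start & tt < win$end
}

#' Write a cohort to per-subject CSV/JSON bundles
#'
#' Layout: one directory per subject and condition containing `eeg.csv`
#' (time_s, F3, F4, FPz, Oz), `gaze_left.csv`/`gaze_right.csv`
#' (time_s, x, y, valid), `head.csv` (time_s, x_deg, y_deg), plus a shared
#' `layout.json` and `truth.json` at the root.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- cohort$layout
  jsonlite::write_json(
    list(total_duration_s = lay$total_duration, deer_frac = lay$deer_frac,
         kid_frac = lay$kid_frac, pre_window_s = lay$pre_window,
         window_length_s = cohort$window_length),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$truth[!vapply(cohort$truth, is.null, TRUE)],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(cohort$subjects)) {
    for (cond in names(cohort$subjects[[s]])) {
      b <- cohort$subjects[[s]][[cond]]
      d <- file.path(dir, s, cond)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(b$eeg)) {
        df <- data.frame(time_s = rec_time(b$eeg), b$eeg$values)
        utils::write.csv(df, file.path(d, "eeg.csv"), row.names = FALSE)
      }
      if (!is.null(b$gaze)) {
        for (eye in c("left", "right")) {
          g <- b$gaze[[eye]]
          utils::write.csv(
            data.frame(time_s = g$time, x = g$yaw, y = g$pitch,
                       valid = as.integer(g$valid)),
            file.path(d, sprintf("gaze_%s.csv", eye)), row.names = FALSE)
        }
      }
      if (!is.null(b$head)) {
        n <- length(b$head$x_deg)
        utils::write.csv(
          data.frame(time_s = (seq_len(n) - 1) / b$head$rate,
                     x_deg = b$head$x_deg, y_deg = b$head$y_deg),
          file.path(d, "head.csv"), row.names = FALSE)
      }
      if (!is.null(b$blinks))
        utils::write.csv(as.data.frame(b$blinks),
                         file.path(d, "blinks.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}
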