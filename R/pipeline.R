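# Orchestration: generate (or load) a cohort, run the EEG, oculomotor and
# multifractal stages, assemble the long-format measures table, and run
# the Condition x Route-event statistics with figure-style summaries.

#' Process one EEG recording into event-level FAA and arousal
#'
#' Full chain: band-pass 7-48 Hz -> 2 s / 1 s epochs (F3, F4) ->
#' +/-100 uV rejection -> Welch band powers -> FAA / arousal -> 3 SD
#' outlier removal per measure -> 4-segment averaging -> event cells
#' (Smooth = mean of the two smooth segments, Deer = segment 2,
#' Kid = segment 4).
#'
#' @param rec a [recording()] with channels F3 and F4.
#' @param layout a [ride_layout()].
#' @return data.frame: event, faa, arousal (one row per event level).
#' @export
process_eeg <- function(rec, layout) {
  segs <- eeg_segments(layout)
  filt <- eeg_bandpass(rec)
  ep <- make_epochs(filt, channels = c("F3", "F4"))
  ep <- reject_amplitude(ep)
  feats <- epoch_features(ep)
  cells <- lapply(c(faa = "faa", arousal = "arousal"), function(meas) {
    v <- feats[[meas]]
    v[!remove_outliers(v)] <- NA
    sm <- segment_means(feats$epoch_onset, v, segs)
    smooth_mean <- mean(sm$mean[sm$label == "smooth"], na.rm = TRUE)
    c(Smooth = if (is.nan(smooth_mean)) NA_real_ else smooth_mean,
      Deer = sm$mean[2], Kid = sm$mean[4])
  })
  data.frame(event = c("Smooth", "Deer", "Kid"),
             faa = unname(cells$faa), arousal = unname(cells$arousal))
}

#' Spectrum width of a displacement series per event window
#'
#' Cuts the three equal-length event windows out of a displacement series
#' and returns the Chhabra-Jensen spectrum width of each.
#'
#' @param x displacement series (degrees).
#' @param rate sampling rate in Hz.
#' @param windows data.frame from [event_windows()].
#' @param config an [mf_config()].
#' @return data.frame: event, width.
#' @export
window_widths <- function(x, rate, windows, config = mf_config()) {
  tt <- (seq_along(x) - 1) / rate
  w <- vapply(seq_len(nrow(windows)), function(i) {
    seg <- x[tt >= windows$start[i] & tt < windows$end[i]]
    if (length(seg) < 65) return(NA_real_)
    sp <- tryCatch(chhabra_jensen(seg, config), error = function(e) NULL)
    if (is.null(sp)) NA_real_ else spectrum_width(sp)
  }, numeric(1))
  data.frame(event = windows$event, width = w)
}

#' Spectrum width of a cleaned gaze trace per event window
#'
#' The measure weights are the magnitudes of the 2-D angular increments,
#' sqrt(dyaw^2 + dpitch^2), so both gaze components contribute to one
#' spectrum per eye. Increments touching residual invalid samples
#' (blinks and other measurement-error runs) carry no eye-movement
#' information and are dropped from the measure rather than bridged —
#' a linear bridge would inject artificial box mass proportional to the
#' blink count.
#'
#' @param trace a cleaned [gaze_trace()].
#' @param windows data.frame from [event_windows()].
#' @param config an [mf_config()].
#' @return data.frame: event, width.
#' @export
gaze_window_widths <- function(trace, windows, config = mf_config()) {
  w <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- trace$time >= windows$start[i] & trace$time < windows$end[i]
    if (sum(sel) < 65) return(NA_real_)
    yaw <- trace$yaw[sel]; pitch <- trace$pitch[sel]
    inc <- sqrt(diff(yaw)^2 + diff(pitch)^2)
    inc <- inc[!is.na(inc)]
    if (length(inc) < 64) return(NA_real_)
    sp <- tryCatch(chhabra_jensen(inc, config, input = "increments"),
                   error = function(e) NULL)
    if (is.null(sp)) NA_real_ else spectrum_width(sp)
  }, numeric(1))
  data.frame(event = windows$event, width = w)
}

event_label_map <- c(smooth = "Smooth", deer = "Deer", kid = "Kid")

#' Run the full pipeline on a cohort
#'
#' For every subject and condition: EEG features (faa, arousal),
#' multifractal widths of left/right gaze and head x/y, and blink counts
#' per event window — assembled into one long-format table, then per
#' measure a Condition x Route-event repeated-measures ANOVA, Tukey post
#' hocs on the event factor, and mean +/- 95% CI summaries.
#'
#' @param cohort a [gen_cohort()] result (or [read_cohort()] output).
#' @param measures subset of c("faa", "arousal", "mfsw_eye_left",
#'   "mfsw_eye_right", "mfsw_head_x", "mfsw_head_y", "blink"); default all
#'   for which the cohort carries raw data.
#' @param mf an [mf_config()].
#' @param verbose log stage progress and per-subject exclusions.
#' @return object of class `ride_results`: list with `measures`
#'   (long-format data.frame), `anova` (named list of `anova_result`),
#'   `posthoc` (named list), `summary` (per measure x condition x event).
#' @export
run_pipeline <- function(cohort, measures = NULL, mf = mf_config(),
                         verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  layout <- cohort$layout
  wins <- event_windows(layout, cohort$window_length)
  rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (s in names(cohort$subjects)) {
    for (cond in names(cohort$subjects[[s]])) {
      b <- cohort$subjects[[s]][[cond]]
      add <- function(measure, event, value)
        rows[[length(rows) + 1]] <<- data.frame(
          subject = s, condition = cond, event = event,
          measure = measure, value = value)
      if (!is.null(b$eeg)) {
        fe <- process_eeg(b$eeg, layout)
        add("faa", fe$event, fe$faa)
        add("arousal", fe$event, fe$arousal)
      }
      if (!is.null(b$gaze)) {
        cl <- lapply(b$gaze, clean_gaze)
        for (eye in c("left", "right")) {
          ww <- gaze_window_widths(cl[[eye]], wins, mf)
          add(paste0("mfsw_eye_", eye), event_label_map[ww$event],
              ww$width)
        }
        bl <- detect_blinks(cl$left, cl$right)
        bf <- blink_frequency(bl, wins)
        add("blink", event_label_map[bf$event], as.numeric(bf$blinks))
      } else if (!is.null(b$blinks)) {
        bf <- blink_frequency(b$blinks, wins)
        add("blink", event_label_map[bf$event], as.numeric(bf$blinks))
      }
      if (!is.null(b$head)) {
        for (ax in c("x", "y")) {
          ww <- window_widths(b$head[[paste0(ax, "_deg")]], b$head$rate,
                              wins, mf)
          add(paste0("mfsw_head_", ax), event_label_map[ww$event],
              ww$width)
        }
      }
    }
    say("processed subject %s", s)
  }
  if (length(rows) == 0) stop("no measures could be computed")
  long <- do.call(rbind, rows)
  if (!is.null(measures)) long <- long[long$measure %in% measures, ]
  if (nrow(long) == 0) stop("final measures table is empty")

  anovas <- list(); posthocs <- list()
  for (meas in unique(long$measure)) {
    sub <- long[long$measure == meas, c("subject", "condition", "event",
                                        "value")]
    anovas[[meas]] <- tryCatch(rm_anova(sub), error = function(e) {
      say("ANOVA for %s failed: %s", meas, conditionMessage(e)); NULL
    })
    posthocs[[meas]] <- tryCatch(tukey_posthoc(sub, "event"),
                                 error = function(e) NULL)
  }
  structure(list(measures = long, anova = anovas, posthoc = posthocs,
                 summary = summarize_measures(long)),
            class = "ride_results")
}

#' Figure-style summary table
#'
#' One row per measure x condition x event with n, mean and the 95% CI
#' half-width across subjects (the error bars of the result figures).
#'
#' @param long long-format measures data.frame (subject, condition,
#'   event, measure, value).
#' @return summary data.frame.
#' @export
summarize_measures <- function(long) {
  cells <- split(long, list(long$measure, long$condition, long$event),
                 drop = TRUE)
  out <- lapply(cells, function(d) {
    ci <- ci95(d$value)
    data.frame(measure = d$measure[1], condition = d$condition[1],
               event = d$event[1], n = ci$n, mean = ci$mean,
               ci95 = ci$ci95)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$measure, out$condition, out$event), ]
}

#' @export
print.ride_results <- function(x, ...) {
  cat("ride_results:", length(unique(x$measures$subject)), "subjects,",
      length(x$anova), "measures\n")
  for (m in names(x$anova)) {
    cat("\n==", m, "==\n")
    if (!is.null(x$anova[[m]])) print(x$anova[[m]])
  }
  invisible(x)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `cohort` object (raw streams only; no truth is required).
#' @export
read_cohort <- function(dir) {
  lay <- jsonlite::read_json(file.path(dir, "layout.json"),
                             simplifyVector = TRUE)
  layout <- ride_layout(lay$total_duration_s, lay$deer_frac, lay$kid_frac,
                        lay$pre_window_s)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"),
                        simplifyVector = TRUE)
  subjects <- list()
  for (s in sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))) {
    conds <- list()
    for (cond in sort(list.dirs(file.path(dir, s), recursive = FALSE,
                                full.names = FALSE))) {
      d <- file.path(dir, s, cond)
      b <- list()
      f <- file.path(d, "eeg.csv")
      if (file.exists(f)) {
        df <- utils::read.csv(f)
        rate <- 1 / stats::median(diff(df$time_s))
        b$eeg <- recording(as.matrix(df[, -1]), rate = round(rate),
                           t0 = df$time_s[1])
      }
      gz <- list()
      for (eye in c("left", "right")) {
        f <- file.path(d, sprintf("gaze_%s.csv", eye))
        if (file.exists(f)) {
          df <- utils::read.csv(f)
          rate <- round(1 / stats::median(diff(df$time_s)))
          gz[[eye]] <- gaze_trace(df$time_s, df$x, df$y,
                                  valid = df$valid > 0, rate = rate)
        }
      }
      if (length(gz) == 2) b$gaze <- gz
      f <- file.path(d, "head.csv")
      if (file.exists(f)) {
        df <- utils::read.csv(f)
        rate <- round(1 / stats::median(diff(df$time_s)))
        b$head <- list(rate = rate, x_deg = df$x_deg, y_deg = df$y_deg)
      }
      f <- file.path(d, "blinks.csv")
      if (file.exists(f)) b$blinks <- as.matrix(utils::read.csv(f))
      conds[[cond]] <- b
    }
    subjects[[s]] <- conds
  }
  structure(list(subjects = subjects, layout = layout,
                 window_length = lay$window_length_s, truth = truth),
            class = "cohort")
}

#' Write pipeline outputs and a run manifest
#'
#' Emits `measures.csv`, `anova.csv`, `posthoc.csv`, `summary.csv` and a
#' machine-readable `manifest.json` (seed, configuration, package
#' version) to `dir`.
#'
#' @param results a `ride_results` object.
#' @param dir output directory.
#' @param seed the seed the run used (recorded in the manifest).
#' @param config optional configuration list echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, seed = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  an <- do.call(rbind, lapply(names(results$anova), function(m) {
    a <- results$anova[[m]]
    if (is.null(a)) return(NULL)
    cbind(measure = m, a$effects)
  }))
  if (!is.null(an))
    utils::write.csv(an, file.path(dir, "anova.csv"), row.names = FALSE)
  ph <- do.call(rbind, lapply(names(results$posthoc), function(m) {
    p <- results$posthoc[[m]]
    if (is.null(p)) return(NULL)
    cbind(measure = m, p)
  }))
  if (!is.null(ph))
    utils::write.csv(ph, file.path(dir, "posthoc.csv"), row.names = FALSE)
  utils::write.csv(results$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(package = "ridephysio",
         version = as.character(utils::packageVersion("ridephysio")),
         seed = seed, config = config,
         n_measures = length(results$anova)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
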