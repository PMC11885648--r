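# EEG preprocessing and feature chain: band-pass filtering, overlapping
# epoching, amplitude-based artifact rejection, Welch band powers, and the
# two per-epoch indices — affectivity (frontal alpha asymmetry, FAA) and
# arousal — followed by per-participant outlier removal and route-segment
# averaging.

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, default 7-48 Hz
#' with a 9th-order one-way design. Zero-phase filtering preserves epoch
#' anchoring; the effective attenuation is that of the squared magnitude
#' response. An optional `correct` hook is applied to the raw values first
#' (the slot where an external artifact correction such as ICA would sit).
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz (defaults 7 and 48).
#' @param order one-way filter order (default 9).
#' @param correct optional function(matrix) -> matrix applied before
#'   filtering.
#' @return filtered [recording()].
#' @export
eeg_bandpass <- function(rec, low = 7, high = 48, order = 9,
                         correct = NULL) {
  stopifnot(inherits(rec, "recording"), low < high)
  if (high >= rec$rate / 2)
    stop("high cutoff at or above Nyquist for this sampling rate")
  v <- rec$values
  if (!is.null(correct)) v <- correct(v)
  out <- rec
  out$values <- filter_zerophase(v, rec$rate, order, low = low, high = high)
  colnames(out$values) <- rec$channel_names
  out
}

#' Cut overlapping fixed-length epochs
#'
#' Epochs of `length` seconds advancing by `step` seconds (default 2 s
#' windows with 1 s overlap). The count is floor((N - L)/S) + 1 in
#' samples; a trailing partial window is discarded.
#'
#' @param rec a [recording()].
#' @param length epoch length in seconds (default 2).
#' @param step hop between epoch onsets in seconds (default 1).
#' @param channels channels to keep (default all).
#' @return object of class `epoch_set`: list with `epochs` (sample x
#'   channel x epoch array), `onsets` (s), `rate`, `retained` mask.
#' @export
make_epochs <- function(rec, length = 2, step = 1, channels = NULL) {
  stopifnot(inherits(rec, "recording"))
  L <- round(length * rec$rate)
  S <- round(step * rec$rate)
  N <- nrow(rec$values)
  if (N < L) stop("recording shorter than one epoch")
  if (is.null(channels)) channels <- rec$channel_names
  v <- rec$values[, channels, drop = FALSE]
  n_ep <- (N - L) %/% S + 1L
  starts <- (seq_len(n_ep) - 1L) * S + 1L
  ep <- array(NA_real_, c(L, base::length(channels), n_ep),
              dimnames = list(NULL, channels, NULL))
  for (i in seq_len(n_ep))
    ep[, , i] <- v[starts[i]:(starts[i] + L - 1L), , drop = FALSE]
  structure(list(epochs = ep, onsets = rec$t0 + (starts - 1L) / rec$rate,
                 rate = rec$rate, epoch_length = length, step = step,
                 retained = rep(TRUE, n_ep)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs of %g s (step %g s), %d retained\n",
              dim(x$epochs)[3], x$epoch_length, x$step, sum(x$retained)))
  invisible(x)
}

#' Reject epochs by amplitude range
#'
#' Drops every epoch in which any channel sample leaves the
#' \[-threshold, +threshold\] microvolt range (movement/blink artifacts).
#' The update is an AND with the existing mask, so rejection is monotone
#' and idempotent: re-applying never re-admits an epoch.
#'
#' @param epochs an `epoch_set`.
#' @param threshold amplitude bound in microvolts (default 100).
#' @return the `epoch_set` with an updated `retained` mask.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  mx <- apply(abs(epochs$epochs), 3, max)
  epochs$retained <- epochs$retained & (mx <= threshold)
  epochs
}

band_lookup <- function(band) {
  if (is.character(band)) {
    tab <- eeg_band_table()
    if (!band %in% names(tab)) stop("unknown band: ", band)
    tab[[band]]
  } else {
    stopifnot(length(band) == 2, band[1] < band[2])
    band
  }
}

#' Band power of a signal
#'
#' Welch PSD integrated over a closed frequency band (bins assigned by
#' center frequency, power = sum of PSD bins times the bin width). For a
#' pure in-band sinusoid of amplitude A the result is close to A^2/2.
#'
#' @param x numeric vector (one epoch of one channel), or a matrix whose
#'   columns are epochs.
#' @param rate sampling rate in Hz.
#' @param band `"alpha"` (8-12), `"beta"` (13-30), `"gamma"` (30-45) or a
#'   numeric c(lo, hi) within (0, rate/2).
#' @param window_sec Welch window length in seconds (default 1).
#' @return nonnegative power (uV^2); vector over columns for matrix input.
#' @export
band_power <- function(x, rate, band, window_sec = 1) {
  b <- band_lookup(band)
  if (b[2] >= rate / 2) stop("band extends to or beyond Nyquist")
  w <- psd_welch(x, rate, window_sec = window_sec)
  sel <- w$freq >= b[1] & w$freq <= b[2]
  if (!any(sel)) stop("no frequency bins inside the requested band")
  df <- w$freq[2] - w$freq[1]
  if (is.null(dim(w$psd))) sum(w$psd[sel]) * df
  else colSums(w$psd[sel, , drop = FALSE]) * df
}

#' Frontal alpha asymmetry
#'
#' Affectivity index: difference of the log10-transformed alpha powers at
#' F4 and F3. Positive values index relatively stronger right-hemisphere
#' alpha, i.e. more approach/positive affect.
#'
#' @param alpha_f4,alpha_f3 alpha-band powers (uV^2).
#' @return log10(alpha_f4) - log10(alpha_f3); NA when either power is not
#'   strictly positive.
#' @export
faa <- function(alpha_f4, alpha_f3) {
  out <- ifelse(alpha_f4 > 0 & alpha_f3 > 0,
                log10(alpha_f4) - log10(alpha_f3), NA_real_)
  unname(out)
}

#' Arousal band-power ratio
#'
#' Ratio of the beta+gamma PSD to the alpha PSD at the averaged frontal
#' electrodes: each band's power is first averaged across F3 and F4, then
#' the ratio (beta + gamma) / alpha is formed. Invariant under global
#' rescaling of all powers.
#'
#' @param alpha,beta,gamma band powers; each a vector over electrodes
#'   (F3, F4) or an already-averaged scalar.
#' @return (mean(beta) + mean(gamma)) / mean(alpha); NA if mean alpha
#'   power is not strictly positive.
#' @export
arousal <- function(alpha, beta, gamma) {
  a <- mean(alpha)
  if (!is.finite(a) || a <= 0) return(NA_real_)
  (mean(beta) + mean(gamma)) / a
}

#' Per-epoch affectivity and arousal
#'
#' Computes Welch band powers at F3 and F4 for every epoch and derives the
#' FAA and arousal indices. Non-retained epochs get NA features.
#'
#' @param epochs an `epoch_set` containing channels F3 and F4.
#' @return data.frame: epoch_onset, faa, arousal, retained.
#' @export
epoch_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"),
            all(c("F3", "F4") %in% dimnames(epochs$epochs)[[2]]))
  n_ep <- dim(epochs$epochs)[3]
  pw <- lapply(c(F3 = "F3", F4 = "F4"), function(ch) {
    m <- epochs$epochs[, ch, ]                 # sample x epoch matrix
    if (is.null(dim(m))) m <- matrix(m, ncol = n_ep)
    vapply(c("alpha", "beta", "gamma"),
           function(b) band_power(m, epochs$rate, b), numeric(n_ep))
  })
  fa <- faa(pw$F4[, "alpha"], pw$F3[, "alpha"])
  ar <- vapply(seq_len(n_ep), function(i)
    arousal(c(pw$F3[i, "alpha"], pw$F4[i, "alpha"]),
            c(pw$F3[i, "beta"], pw$F4[i, "beta"]),
            c(pw$F3[i, "gamma"], pw$F4[i, "gamma"])), numeric(1))
  fa[!epochs$retained] <- NA
  ar[!epochs$retained] <- NA
  data.frame(epoch_onset = epochs$onsets, faa = fa, arousal = ar,
             retained = epochs$retained)
}

#' Outlier mask by individual mean and SD
#'
#' Single-pass rule: a value is an outlier when it deviates from the mean
#' of the supplied values (one participant's epochs of one measure) by at
#' least `k` standard deviations. Mean and SD are computed once over the
#' non-missing values; the rule is not re-iterated, so the mask is
#' idempotent when re-applied to the kept values' original statistics.
#' With SD = 0 nothing is removed.
#'
#' @param x numeric vector (one participant, one measure).
#' @param k SD multiplier (default 3).
#' @return logical keep-mask, same length as `x` (NA values are dropped).
#' @export
remove_outliers <- function(x, k = 3) {
  keep <- !is.na(x)
  if (sum(keep) < 2) return(keep)
  m <- mean(x[keep])
  s <- stats::sd(x[keep])
  if (s == 0) return(keep)
  keep & (abs(x - m) / s < k)
}

#' Per-segment means of epoch values
#'
#' Averages retained, non-outlier epoch values into route segments, each
#' epoch assigned by its onset. Empty segments yield NA (a missing cell
#' propagated to the statistics stage).
#'
#' @param onsets epoch onset times (s).
#' @param values epoch values (NA = excluded).
#' @param segments data.frame from [eeg_segments()] (or any frame with
#'   start/end and a label column).
#' @return `segments` with an added `mean` (and `n`) column.
#' @export
segment_means <- function(onsets, values, segments) {
  out <- segments
  out$mean <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(segments))) {
    sel <- onsets >= segments$start[i] & onsets < segments$end[i] &
      !is.na(values)
    out$n[i] <- sum(sel)
    if (any(sel)) out$mean[i] <- mean(values[sel])
  }
  out
}
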