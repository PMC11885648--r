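# Shared signal-processing primitives: zero-phase Butterworth-magnitude
# filtering (frequency domain) and Welch power spectral density.

#' Squared Butterworth magnitude response
#'
#' Gain applied by a forward-backward (zero-phase) Butterworth filter of the
#' given order: the squared magnitude of the analog prototype, evaluated at
#' the requested frequencies.
#'
#' @param f numeric vector of frequencies (Hz, nonnegative).
#' @param order filter order n of the one-way filter.
#' @param low,high band edges in Hz. Supply only `high` for a low-pass,
#'   only `low` for a high-pass, both for a band-pass.
#' @return numeric vector of gains in \[0, 1\].
#' @keywords internal
butter_gain2 <- function(f, order, low = NULL, high = NULL) {
  stopifnot(!is.null(low) || !is.null(high))
  if (!is.null(low) && !is.null(high)) {       # band-pass
    w  <- 2 * pi * f
    wl <- 2 * pi * low
    wh <- 2 * pi * high
    w0sq <- wl * wh
    bw   <- wh - wl
    r <- ifelse(w == 0, Inf, (w^2 - w0sq) / (w * bw))
    g <- 1 / (1 + r^(2 * order))
    g[f == 0] <- 0
  } else if (!is.null(high)) {                  # low-pass
    g <- 1 / (1 + (f / high)^(2 * order))
  } else {                                      # high-pass
    g <- ifelse(f == 0, 0, 1 / (1 + (low / f)^(2 * order)))
  }
  g
}

#' Zero-phase Butterworth filtering of uniformly sampled series
#'
#' Applies the squared Butterworth magnitude response (the gain of one
#' forward and one backward pass) in the frequency domain, which yields an
#' exactly zero-phase filter with no start-up transients. Operates on a
#' vector or column-wise on a matrix.
#'
#' @param x numeric vector or matrix (series in columns).
#' @param rate sampling rate in Hz.
#' @param order one-way filter order.
#' @param low,high band edges in Hz (see [butter_gain2()]).
#' @return filtered object of the same shape as `x`.
#' @export
filter_zerophase <- function(x, rate, order, low = NULL, high = NULL) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  # mirror-pad so the implicit circular signal is continuous at the ends
  # (otherwise a level difference between start and end rings as an edge
  # artifact, like unpadded filtfilt)
  xp <- rbind(xm[n:1, , drop = FALSE], xm, xm[n:1, , drop = FALSE])
  m <- 3L * n
  freqs <- seq_len(m) - 1
  freqs <- pmin(freqs, m - freqs) * rate / m   # two-sided -> folded Hz
  g <- butter_gain2(freqs, order = order, low = low, high = high)
  out <- Re(stats::mvfft(stats::mvfft(xp) * g, inverse = TRUE)) / m
  out <- out[(n + 1):(2 * n), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Welch power spectral density
#'
#' One-sided PSD by averaging modified periodograms of Hann-windowed,
#' 50%-overlapping segments. With the default 1-s window the frequency
#' resolution is 1 Hz, enough to resolve the 8 Hz alpha edge.
#'
#' @param x numeric vector, or a matrix whose columns are independent series
#'   (all columns share the returned frequency axis).
#' @param rate sampling rate in Hz.
#' @param window_sec segment length in seconds (default 1).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (units^2/Hz; matrix if `x` was
#'   a matrix, columns matching those of `x`).
#' @export
psd_welch <- function(x, rate, window_sec = 1, overlap = 0.5) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  nper <- round(window_sec * rate)
  if (n < nper) stop("series shorter than one Welch window")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1)) / nper))  # periodic Hann
  u <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- matrix(0, nfreq, ncol(xm))
  for (s in starts) {
    seg <- xm[s:(s + nper - 1L), , drop = FALSE] * w
    sp <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + Mod(sp)^2
  }
  psd <- acc / (length(starts) * rate * u)
  # one-sided: double everything but DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  freq <- (seq_len(nfreq) - 1) * rate / nper
  list(freq = freq, psd = if (vec) drop(psd) else psd)
}

# run-length encoding of a logical vector as [start, end] index pairs
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
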