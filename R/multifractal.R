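# Chhabra-Jensen direct estimation of the multifractal singularity
# spectrum f(alpha) and its width. The method avoids the Legendre
# transform: for each moment order q and box size eps it forms normalized
# q-weighted box measures
#     mu_i(q, eps) = P_i(eps)^q / sum_j P_j(eps)^q
# and reads the Hoelder exponent alpha(q) off the scaling of
# sum_i mu_i log P_i against log eps, and the singularity dimension f(q)
# off the scaling of sum_i mu_i log mu_i against log eps.

#' Multifractal estimation configuration
#'
#' @param qmin,qmax,qstep moment-order grid (default -5 to 5 in steps of
#'   0.25; must bracket 0 and 1). Negative q probe the sparse regions of
#'   the measure and dominate the estimated width; the +/-5 range keeps
#'   their variance bounded while covering widths in the range seen for
#'   displacement data.
#' @param scales box sizes in samples; default dyadic from 8 up to N/8 so
#'   every scale yields at least 8 boxes.
#' @param min_r2 diagnostic floor for the per-q regression R^2; spectra are
#'   never censored by it, it is only reported.
#' @return object of class `mf_config`.
#' @export
mf_config <- function(qmin = -5, qmax = 5, qstep = 0.25, scales = NULL,
                      min_r2 = 0.9) {
  q <- seq(qmin, qmax, by = qstep)
  if (!any(abs(q) < 1e-12) || !any(abs(q - 1) < 1e-12))
    stop("q grid must contain 0 and 1")
  structure(list(q = q, scales = scales, min_r2 = min_r2),
            class = "mf_config")
}

default_scales <- function(n) {
  s <- 8L
  out <- integer(0)
  while (n %/% s >= 8L) { out <- c(out, s); s <- s * 2L }
  out
}

#' Box probabilities of a series at one scale
#'
#' The measure is built from absolute first differences of the series (the
#' standard adaptation of the box measure to displacement time series):
#' each box of `scale` consecutive increments carries the normalized sum of
#' their magnitudes. Pass `differenced = FALSE` for inputs that already are
#' a measure or nonnegative increment magnitudes.
#'
#' @param x numeric series (or measure, see `differenced`).
#' @param scale box size in samples.
#' @param differenced take |diff(x)| first (default TRUE).
#' @return numeric vector of box probabilities summing to 1; zero-mass
#'   boxes are dropped.
#' @export
build_measure <- function(x, scale, differenced = TRUE) {
  w <- if (differenced) abs(diff(x)) else x
  if (any(w < 0)) stop("measure weights must be nonnegative")
  n <- (length(w) %/% scale) * scale
  if (n < scale) stop("series too short for this scale")
  tot <- sum(w[1:n])
  if (tot == 0) stop("degenerate input: all-constant series has no measure")
  p <- colSums(matrix(w[1:n], nrow = scale)) / tot
  p[p > 0]
}

#' Chhabra-Jensen multifractal spectrum
#'
#' Estimates alpha(q) and f(q) by ordinary least squares of the q-weighted
#' box sums against log(eps/N) across scales, together with per-q
#' regression R^2 diagnostics and the spectrum width
#' \eqn{\Delta\alpha = \max_q \alpha(q) - \min_q \alpha(q)}.
#'
#' Numerical handling: the q-th powers are formed in the log domain with a
#' max-subtraction (log-sum-exp) normalization, so extreme q never overflow
#' and are never clipped. Zero-mass boxes are excluded from all sums: they
#' contribute nothing for q > 0 and would be singular for q < 0. The
#' series is truncated to the largest length divisible by the maximal
#' scale so that no partial boxes enter.
#'
#' @param x input series, or a measure / increment-magnitude vector.
#' @param config an [mf_config()].
#' @param input `"series"` (take absolute first differences),
#'   `"increments"` (nonnegative magnitudes, used as-is), or `"measure"`
#'   (already normalized box masses, used as-is).
#' @return object of class `mf_spectrum`: data.frame-like list with
#'   `q`, `alpha`, `f`, `r2_alpha`, `r2_f`, the `scales` used and `width`.
#' @export
chhabra_jensen <- function(x, config = mf_config(),
                           input = c("series", "increments", "measure")) {
  input <- match.arg(input)
  stopifnot(inherits(config, "mf_config"))
  w <- switch(input, series = abs(diff(x)), increments = x, measure = x)
  if (any(!is.finite(w))) stop("input contains non-finite values")
  if (any(w < 0)) stop("measure weights must be nonnegative")
  if (sum(w) == 0)
    return(degenerate_spectrum(config, length(w)))
  scales <- config$scales
  if (is.null(scales)) scales <- default_scales(length(w))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 3) stop("need at least 3 usable scales")
  n_use <- (length(w) %/% max(scales)) * max(scales)
  if (n_use < max(scales)) stop("series too short for the maximal scale")
  w <- w[1:n_use]

  q <- config$q
  le <- log(scales / n_use)                 # log box size, relative
  num_a <- matrix(NA_real_, length(q), length(scales))
  num_f <- matrix(NA_real_, length(q), length(scales))
  for (s in seq_along(scales)) {
    p <- build_measure(w, scales[s], differenced = FALSE)
    lp <- log(p)
    for (k in seq_along(q)) {
      a <- q[k] * lp
      m <- max(a)
      lz <- m + log(sum(exp(a - m)))        # log sum p^q, overflow-safe
      lmu <- a - lz
      mu <- exp(lmu)
      num_a[k, s] <- sum(mu * lp)
      num_f[k, s] <- sum(mu * lmu)
    }
  }
  fit <- function(y) {                      # OLS slope + R^2 against le
    sl <- stats::cov(le, y) / stats::var(le)
    r <- suppressWarnings(stats::cor(le, y))
    c(slope = sl, r2 = if (is.na(r)) 1 else r^2)
  }
  fa <- t(apply(num_a, 1, fit))
  ff <- t(apply(num_f, 1, fit))
  alpha <- fa[, 1]
  structure(list(q = q, alpha = alpha, f = ff[, 1],
                 r2_alpha = fa[, 2], r2_f = ff[, 2],
                 scales = scales, n = n_use,
                 width = max(alpha) - min(alpha),
                 degenerate = FALSE),
            class = "mf_spectrum")
}

degenerate_spectrum <- function(config, n) {
  q <- config$q
  structure(list(q = q, alpha = rep(NA_real_, length(q)),
                 f = rep(NA_real_, length(q)),
                 r2_alpha = rep(NA_real_, length(q)),
                 r2_f = rep(NA_real_, length(q)),
                 scales = integer(0), n = n, width = NA_real_,
                 degenerate = TRUE),
            class = "mf_spectrum")
}

#' Width of a multifractal spectrum
#'
#' @param spec an `mf_spectrum`.
#' @return \eqn{\Delta\alpha = \max \alpha(q) - \min \alpha(q)}; NA for a
#'   degenerate spectrum.
#' @export
spectrum_width <- function(spec) {
  stopifnot(inherits(spec, "mf_spectrum"))
  if (isTRUE(spec$degenerate)) return(NA_real_)
  max(spec$alpha) - min(spec$alpha)
}

#' Closed-form binomial-cascade spectrum
#'
#' Theoretical alpha(q) and f(q) of the two-scale binomial cascade with
#' multiplier p, used as the estimator's oracle:
#' \deqn{\alpha(q) = -\frac{p^q \ln p + (1-p)^q \ln(1-p)}{(p^q+(1-p)^q)\ln 2}}
#' \deqn{f(q) = q\,\alpha(q) + \log_2(p^q + (1-p)^q)}
#'
#' @param p cascade multiplier in (0, 1).
#' @param q numeric vector of moment orders.
#' @return data.frame with q, alpha, f.
#' @export
binomial_spectrum_theory <- function(p, q) {
  pq <- p^q
  rq <- (1 - p)^q
  alpha <- -(pq * log(p) + rq * log(1 - p)) / ((pq + rq) * log(2))
  f <- q * alpha + log2(pq + rq)
  data.frame(q = q, alpha = alpha, f = f)
}

#' @export
print.mf_spectrum <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate multifractal spectrum (constant input)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Chhabra-Jensen spectrum: %d q values in [%.2f, %.2f], %d scales (%d-%d)\n",
    length(x$q), min(x$q), max(x$q), length(x$scales),
    min(x$scales), max(x$scales)))
  cat(sprintf("  width = %.4f   min R^2(alpha) = %.3f\n",
              x$width, min(x$r2_alpha)))
  invisible(x)
}

#' @export
as.data.frame.mf_spectrum <- function(x, ...) {
  data.frame(q = x$q, alpha = x$alpha, f = x$f,
             r2_alpha = x$r2_alpha, r2_f = x$r2_f)
}
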