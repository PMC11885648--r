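# Inferential layer: two-way fully within-subject ANOVA with the
# classical sums-of-squares decomposition, generalized eta-squared effect
# sizes, Tukey-adjusted pairwise post hocs on subject-level collapsed
# differences, and 95% confidence summaries.

check_cell_table <- function(table) {
  need <- c("subject", "condition", "event", "value")
  if (!all(need %in% names(table)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  table$subject <- as.character(table$subject)
  table$condition <- as.character(table$condition)
  table$event <- as.character(table$event)
  dup <- duplicated(table[c("subject", "condition", "event")])
  if (any(dup)) stop("more than one value per subject x condition x event")
  # listwise deletion of subjects with any missing cell
  a <- sort(unique(table$condition))
  b <- sort(unique(table$event))
  full <- length(a) * length(b)
  ok <- vapply(split(table, table$subject), function(d)
    nrow(d[!is.na(d$value), ]) == full &&
      nrow(unique(d[c("condition", "event")])) == full, logical(1))
  dropped <- names(ok)[!ok]
  table <- table[table$subject %in% names(ok)[ok], ]
  if (length(unique(table$subject)) < 2)
    stop("fewer than 2 complete subjects after listwise deletion",
         if (length(dropped))
           paste0(" (incomplete: ", paste(dropped, collapse = ", "), ")"))
  attr(table, "dropped_subjects") <- dropped
  table
}

#' Two-way repeated-measures ANOVA
#'
#' Condition x Route-event ANOVA with both factors within subject.
#' Classical decomposition on the complete balanced table (subjects with
#' any missing cell are dropped listwise): each effect is tested against
#' its own interaction with subjects,
#' F_A = MS_A / MS_AxS, F_B = MS_B / MS_BxS, F_AB = MS_AB / MS_ABxS,
#' with degrees of freedom (a-1, (a-1)(n-1)) and so on. No sphericity
#' correction is applied by default (matching the uncorrected dfs that
#' this design is conventionally reported with); `gg_correction = TRUE`
#' applies Greenhouse-Geisser-corrected p values.
#'
#' @param table data.frame with columns subject, condition, event, value.
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the dfs
#'   used for the p values (default FALSE).
#' @return object of class `anova_result`: `effects` data.frame (effect,
#'   df_num, df_den, ss, ms, F, p, ges) and `ss` (full decomposition,
#'   including subjects and error strata).
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  table <- check_cell_table(table)
  subj <- factor(table$subject)
  A <- factor(table$condition)
  B <- factor(table$event)
  y <- table$value
  n <- nlevels(subj); a <- nlevels(A); b <- nlevels(B)

  gm <- mean(y)
  ms  <- tapply(y, subj, mean)
  ma  <- tapply(y, A, mean)
  mb  <- tapply(y, B, mean)
  mab <- tapply(y, list(A, B), mean)
  mas <- tapply(y, list(subj, A), mean)
  mbs <- tapply(y, list(subj, B), mean)

  ss_s  <- a * b * sum((ms - gm)^2)
  ss_a  <- n * b * sum((ma - gm)^2)
  ss_b  <- n * a * sum((mb - gm)^2)
  ss_ab <- n * sum((mab - outer(ma - gm, mb - gm, "+") - gm)^2)
  ss_as <- b * sum((mas - outer(ms - gm, ma - gm, "+") - gm)^2)
  ss_bs <- a * sum((mbs - outer(ms - gm, mb - gm, "+") - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  dfs <- list(A = c(a - 1, (a - 1) * (n - 1)),
              B = c(b - 1, (b - 1) * (n - 1)),
              AB = c((a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1)))
  ss_eff <- c(A = ss_a, B = ss_b, AB = ss_ab)
  ss_err <- c(A = ss_as, B = ss_bs, AB = ss_abs)
  noise_pool <- ss_s + ss_as + ss_bs + ss_abs

  eff <- lapply(c("A", "B", "AB"), function(e) {
    df1 <- dfs[[e]][1]; df2 <- dfs[[e]][2]
    msn <- ss_eff[e] / df1
    msd <- ss_err[e] / df2
    f <- if (msd > 0) msn / msd else if (msn == 0) 0 else Inf
    if (msd == 0 && msn == 0) f <- 0
    eps <- 1
    if (gg_correction && e != "A")
      eps <- gg_epsilon(table, e)
    p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    if (msd == 0 && msn == 0) p <- 1
    denom <- ss_eff[e] + noise_pool
    ges <- if (denom > 0) ss_eff[e] / denom else 0
    data.frame(effect = c(A = "condition", B = "event",
                          AB = "condition:event")[e],
               df_num = df1, df_den = df2, ss = unname(ss_eff[e]),
               F = unname(f), p = unname(p), ges = unname(ges))
  })
  structure(list(effects = do.call(rbind, eff),
                 ss = c(subject = ss_s, A = ss_a, B = ss_b, AB = ss_ab,
                        AxS = ss_as, BxS = ss_bs, ABxS = ss_abs,
                        total = ss_tot),
                 n_subjects = n, levels = list(condition = levels(A),
                                               event = levels(B)),
                 dropped = attr(table, "dropped_subjects")),
            class = "anova_result")
}

# Greenhouse-Geisser epsilon for the B or AB stratum
gg_epsilon <- function(table, effect) {
  subj <- factor(table$subject)
  A <- factor(table$condition); B <- factor(table$event)
  if (effect == "B") {
    m <- tapply(table$value, list(subj, B), mean)
  } else {
    # interaction contrasts: per-subject A-difference profiles over B
    wide <- tapply(table$value, list(subj, A, B), mean)
    m <- wide[, 1, ] - wide[, 2, ]
    if (dim(wide)[2] > 2)
      for (j in 3:dim(wide)[2]) m <- cbind(m, wide[, 1, ] - wide[, j, ])
  }
  S <- stats::cov(m)
  k <- ncol(S)
  dc <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
  sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
}

#' Generalized eta-squared
#'
#' Effect size for fully within-subject designs using all subject-related
#' variance in the denominator:
#' ges = SS_effect / (SS_effect + SS_subject + SS_AxS + SS_BxS + SS_ABxS).
#' All-zero data yields 0 by convention.
#'
#' @param result an `anova_result`, or its `ss` decomposition vector.
#' @return named numeric vector of ges per effect.
#' @export
generalized_eta_squared <- function(result) {
  ss <- if (inherits(result, "anova_result")) result$ss else result
  pool <- ss["subject"] + ss["AxS"] + ss["BxS"] + ss["ABxS"]
  out <- vapply(c("A", "B", "AB"), function(e) {
    denom <- ss[e] + pool
    if (denom > 0) unname(ss[e] / denom) else 0
  }, numeric(1))
  names(out) <- c("condition", "event", "condition:event")
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects)\n", x$n_subjects))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-16s F(%d, %d) = %.3f, p = %.4g, ges = %.3f\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i],
                e$ges[i]))
  if (length(x$dropped))
    cat("  dropped (incomplete):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Tukey-adjusted pairwise post hocs
#'
#' For each pair of levels of the tested factor, values are collapsed over
#' the other factor to one mean per subject and level, a paired t test is
#' formed on the subject-level differences (df = n - 1), and the p value
#' is adjusted through the studentized-range distribution with k = number
#' of levels via q = |t| * sqrt(2). With k = 2 this reduces to the
#' unadjusted paired t.
#'
#' @param table data.frame with subject, condition, event, value.
#' @param factor `"event"` or `"condition"`.
#' @return data.frame: level_1, level_2, mean_diff, t, df, p_tukey.
#' @export
tukey_posthoc <- function(table, factor = c("event", "condition")) {
  factor <- match.arg(factor)
  table <- check_cell_table(table)
  lv <- sort(unique(table[[factor]]))
  if (length(lv) < 2) stop("factor has fewer than 2 levels")
  k <- length(lv)
  # per subject x level means, collapsed over the other factor
  m <- tapply(table$value, list(table$subject, table[[factor]]), mean)
  n <- nrow(m)
  pairs <- utils::combn(lv, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    d <- m[, pairs[1, j]] - m[, pairs[2, j]]
    md <- mean(d)
    se <- stats::sd(d) / sqrt(n)
    t <- if (se > 0) md / se else 0
    p <- if (se > 0)
      suppressWarnings(stats::ptukey(abs(t) * sqrt(2), nmeans = k,
                                     df = n - 1, lower.tail = FALSE))
    else 1
    if (is.nan(p)) p <- NA_real_               # ptukey undefined at df = 1
    data.frame(level_1 = pairs[1, j], level_2 = pairs[2, j],
               mean_diff = md, t = t, df = n - 1, p_tukey = p)
  })
  do.call(rbind, out)
}

#' Mean and 95% confidence half-width
#'
#' @param x numeric values (one design cell across subjects).
#' @return list with n, mean, ci95 (half-width, t-based; NA for n < 2).
#' @export
ci95 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(n = 0L, mean = NA_real_, ci95 = NA_real_))
  hw <- if (n >= 2)
    stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  else NA_real_
  list(n = n, mean = mean(x), ci95 = hw)
}
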