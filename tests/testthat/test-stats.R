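# Within-subject ANOVA against independent oracles (brute_force_ss from
# helper-oracles.R and base R aov with an Error stratum), effect sizes,
# post hocs and CIs.

test_that("rm_anova matches the brute-force decomposition on random tables", {
  withr::with_seed(21, for (i in 1:25) {
    tb <- random_cell_table(sample(2:6, 1))
    res <- rm_anova(tb)
    ss <- brute_force_ss(tb)
    expect_equal(unname(res$ss[names(ss)]), unname(ss), tolerance = 1e-8)
    expect_lt(abs(sum(res$ss[c("subject", "A", "B", "AB", "AxS", "BxS",
                               "ABxS")]) - res$ss["total"]), 1e-8)
  })
})

test_that("rm_anova agrees with aov's within-subject strata", {
  tb <- random_cell_table(8, seed = 5)
  res <- rm_anova(tb)
  fit <- summary(stats::aov(
    value ~ condition * event + Error(subject / (condition * event)),
    data = transform(tb, subject = factor(subject),
                     condition = factor(condition),
                     event = factor(event))))
  get_f <- function(stratum, term) {
    t <- fit[[stratum]][[1]]
    t[trimws(rownames(t)) == term, c("F value", "Pr(>F)")]
  }
  e <- res$effects
  fa <- get_f("Error: subject:condition", "condition")
  fb <- get_f("Error: subject:event", "event")
  fab <- get_f("Error: subject:condition:event", "condition:event")
  expect_equal(e$F[e$effect == "condition"], fa[[1]], tolerance = 1e-8)
  expect_equal(e$p[e$effect == "condition"], fa[[2]], tolerance = 1e-8)
  expect_equal(e$F[e$effect == "event"], fb[[1]], tolerance = 1e-8)
  expect_equal(e$F[e$effect == "condition:event"], fab[[1]],
               tolerance = 1e-8)
})

test_that("two-level condition F equals the squared paired t", {
  withr::with_seed(31, for (i in 1:10) {
    tb <- random_cell_table(6)
    res <- rm_anova(tb)
    # paired t on per-subject condition means (collapsed over events)
    m <- tapply(tb$value, list(tb$subject, tb$condition), mean)
    tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(res$effects$F[1], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$effects$p[1], tt$p.value, tolerance = 1e-8)
  })
})

test_that("degenerate and malformed tables are handled", {
  tb <- random_cell_table(4, seed = 1)
  tb$value <- 7
  res <- rm_anova(tb)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p == 1))
  expect_true(all(res$effects$ges == 0))
  # duplicate cell
  expect_error(rm_anova(rbind(tb, tb[1, ])), "more than one value")
  # subject with a missing cell is dropped listwise
  tb2 <- random_cell_table(4, seed = 2)
  tb2$value[tb2$subject == "s01" & tb2$event == "Deer" &
              tb2$condition == "Human"] <- NA
  res2 <- rm_anova(tb2)
  expect_equal(res2$n_subjects, 3)
  expect_equal(res2$dropped, "s01")
  expect_error(rm_anova(tb2[tb2$subject %in% c("s01", "s02"), ]),
               "fewer than 2 complete")
})

test_that("generalized eta-squared follows the pooled-denominator formula", {
  tb <- random_cell_table(6, seed = 41)
  res <- rm_anova(tb)
  ss <- res$ss
  pool <- ss["subject"] + ss["AxS"] + ss["BxS"] + ss["ABxS"]
  ges <- generalized_eta_squared(res)
  expect_equal(unname(ges["condition"]), unname(ss["A"] / (ss["A"] + pool)))
  expect_equal(unname(res$effects$ges),
               unname(ges[c("condition", "event", "condition:event")]))
  expect_true(all(ges >= 0 & ges <= 1))
  # SS_effect equal to the pool -> 0.5 (ratio identity)
  expect_equal(unname(generalized_eta_squared(
    c(subject = 1, A = 4, B = 0, AB = 0, AxS = 1, BxS = 1, ABxS = 1))["condition"]),
    0.5)
})

test_that("ges approaches 1 as planted effect dominates vanishing noise", {
  mk <- function(noise) {
    co <- gen_cohort(6, layout = ride_layout(60), window_length = 8,
                     condition_effect_faa = 0.8, noise_sd = noise,
                     measures = "blink", event_effect_blink = 0.05,
                     seed = 13)
    tb <- run_pipeline(co)$measures
    rm_anova(tb[tb$measure == "blink", ])$effects
  }
  e <- mk(0)
  expect_gt(e$ges[e$effect == "event"], 0.3)   # strong planted event effect
})

test_that("Tukey post hocs reduce to the paired t at k = 2 and adjust at k = 3", {
  tb <- random_cell_table(8, seed = 51)
  ph_c <- tukey_posthoc(tb, "condition")       # k = 2
  m <- tapply(tb$value, list(tb$subject, tb$condition), mean)
  tt <- stats::t.test(m[, "Human"], m[, "SelfDriving"], paired = TRUE)
  expect_equal(ph_c$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(ph_c$p_tukey, tt$p.value, tolerance = 1e-6)

  ph_e <- tukey_posthoc(tb, "event")           # k = 3: adjusted upward
  for (i in seq_len(nrow(ph_e))) {
    praw <- 2 * stats::pt(abs(ph_e$t[i]), df = ph_e$df[i],
                          lower.tail = FALSE)
    expect_gte(ph_e$p_tukey[i] + 1e-12, praw)
    # oracle: studentized range at q = |t| sqrt(2)
    expect_equal(ph_e$p_tukey[i],
                 stats::ptukey(abs(ph_e$t[i]) * sqrt(2), 3, 7,
                               lower.tail = FALSE), tolerance = 1e-12)
  }
  # identical level means -> t = 0, p = 1
  tb0 <- random_cell_table(4, seed = 3)
  tb0$value <- ave(tb0$value, tb0$subject)     # no event differences
  ph0 <- tukey_posthoc(tb0, "event")
  expect_true(all(abs(ph0$t) < 1e-10))
  expect_true(all(ph0$p_tukey > 1 - 1e-6))
})

test_that("ci95 uses the t quantile over sqrt(n)", {
  # n = 4, SD = 2 -> half-width qt(.975, 3) * 2 / 2 = 3.182
  x <- c(-3, -1, 1, 3) / sqrt(20 / 3) * 2 + 5  # mean 5, sd 2
  expect_equal(stats::sd(x), 2)
  ci <- ci95(x)
  expect_equal(ci$ci95, stats::qt(0.975, 3), tolerance = 1e-6)
  expect_equal(ci$mean, 5)
  expect_equal(ci95(rep(2, 5))$ci95, 0)
  expect_true(is.na(ci95(3)$ci95))
  # doubling n at fixed SD shrinks the half-width
  y <- rep(x, 2)
  expect_lt(ci95(y)$ci95, ci$ci95)
})
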