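# Independent oracles used by both the unit and acceptance suites.

# brute-force within-subject decomposition: explicit loops over subjects
# and cells, no tapply/matrix shortcuts
brute_force_ss <- function(tb) {
  subj <- unique(tb$subject); A <- unique(tb$condition)
  B <- unique(tb$event)
  n <- length(subj); a <- length(A); b <- length(B)
  gm <- mean(tb$value)
  ss_s <- 0
  for (s in subj) ss_s <- ss_s + a * b * (mean(tb$value[tb$subject == s]) - gm)^2
  ss_a <- 0
  for (i in A) ss_a <- ss_a + n * b * (mean(tb$value[tb$condition == i]) - gm)^2
  ss_b <- 0
  for (j in B) ss_b <- ss_b + n * a * (mean(tb$value[tb$event == j]) - gm)^2
  ss_ab <- 0
  for (i in A) for (j in B) {
    mij <- mean(tb$value[tb$condition == i & tb$event == j])
    mi <- mean(tb$value[tb$condition == i])
    mj <- mean(tb$value[tb$event == j])
    ss_ab <- ss_ab + n * (mij - mi - mj + gm)^2
  }
  ss_as <- 0
  for (s in subj) for (i in A) {
    msi <- mean(tb$value[tb$subject == s & tb$condition == i])
    ms <- mean(tb$value[tb$subject == s])
    mi <- mean(tb$value[tb$condition == i])
    ss_as <- ss_as + b * (msi - ms - mi + gm)^2
  }
  ss_bs <- 0
  for (s in subj) for (j in B) {
    msj <- mean(tb$value[tb$subject == s & tb$event == j])
    ms <- mean(tb$value[tb$subject == s])
    mj <- mean(tb$value[tb$event == j])
    ss_bs <- ss_bs + a * (msj - ms - mj + gm)^2
  }
  ss_tot <- sum((tb$value - gm)^2)
  c(subject = ss_s, A = ss_a, B = ss_b, AB = ss_ab, AxS = ss_as,
    BxS = ss_bs, ABxS = ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs,
    total = ss_tot)
}
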