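test_that("auroc equals the exhaustive pairwise oracle, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    risk <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    expect_equal(auroc(risk, outcome), auroc_oracle(risk, outcome))
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both outcome classes")
})

test_that("auroc agrees with an independent ROC implementation", {
  set.seed(23)
  for (i in 1:5) {
    risk <- runif(80)
    outcome <- rbinom(80, 1, 0.3)
    if (length(unique(outcome)) < 2) next
    expect_equal(auroc(risk, outcome),
                 as.numeric(pROC::auc(outcome, risk, quiet = TRUE,
                                      direction = "<", levels = c(0, 1))))
  }
})

test_that("stratified weighted AUROC aggregates per-block scores by observation share", {
  # single stratum: equals the plain AUROC
  set.seed(5)
  preds <- data.frame(patient_id = 1:50, block_index = 0L,
                      risk = runif(50), outcome = rbinom(50, 1, 0.4))
  rep1 <- stratified_weighted_auroc(preds)
  expect_equal(rep1$auroc, auroc(preds$risk, preds$outcome))

  # two strata built by hand: AUROC 1.0 (weight 0.6) and 0.5 (weight 0.4)
  s1 <- data.frame(patient_id = 1:6, block_index = 0L,
                   risk = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                   outcome = c(1, 1, 1, 0, 0, 0))
  s2 <- data.frame(patient_id = 1:4, block_index = 1L,
                   risk = c(0.5, 0.5, 0.5, 0.5),
                   outcome = c(1, 1, 0, 0))
  rep2 <- stratified_weighted_auroc(rbind(s1, s2))
  expect_equal(rep2$strata$auroc, c(1.0, 0.5))
  expect_equal(rep2$strata$weight, c(0.6, 0.4))
  expect_equal(rep2$auroc, 0.6 * 1.0 + 0.4 * 0.5)

  # every stratum perfectly ranked
  expect_equal(stratified_weighted_auroc(
    rbind(s1, transform(s1, block_index = 1L)))$auroc, 1.0)
})

test_that("single-class strata are dropped with weights renormalised", {
  s1 <- data.frame(patient_id = 1:4, block_index = 0L,
                   risk = c(0.8, 0.7, 0.2, 0.1), outcome = c(1, 1, 0, 0))
  s2 <- data.frame(patient_id = 1:3, block_index = 1L,
                   risk = c(0.5, 0.4, 0.3), outcome = c(0, 0, 0))
  rep_ <- stratified_weighted_auroc(rbind(s1, s2))
  expect_equal(rep_$dropped, "1")
  expect_equal(sum(rep_$strata$weight), 1)
  expect_equal(rep_$auroc, 1.0)
  expect_error(stratified_weighted_auroc(s2), "no stratum")
})

test_that("patient-level bootstrap: basic interval, whole patients resampled", {
  set.seed(9)
  preds <- data.frame(patient_id = rep(1:40, each = 2),
                      block_index = rep(0:1, 40),
                      risk = runif(80), outcome = rbinom(80, 1, 0.3))
  # constant statistic: zero-width interval at the constant
  bs <- bootstrap_ci(preds, statistic = function(p) 0.42, n_boot = 200, seed = 1)
  expect_equal(bs$ci, c(0.42, 0.42))

  # patients travel whole: every resample keeps patients' two blocks together
  bs2 <- bootstrap_ci(preds, statistic = function(p) {
    stopifnot(all(table(p$patient_id) == 2))
    mean(p$risk)
  }, n_boot = 200, seed = 2)
  expect_lt(bs2$ci[1], mean(preds$risk))
  expect_gt(bs2$ci[2], mean(preds$risk))

  expect_error(bootstrap_ci(preds, n_boot = 50), "n_boot")
  one <- preds[preds$patient_id == 1, ]
  expect_error(bootstrap_ci(one), ">= 2 patients")
})

test_that("bootstrap intervals are stable under more resamples and cover the truth", {
  # truth: large-sample stratified AUROC of the generating risk model
  gen <- function(n, seed) {
    set.seed(seed)
    k <- sample(1:3, n, replace = TRUE)
    pid <- rep(seq_len(n), k)
    blk <- unlist(lapply(k, seq_len)) - 1L
    risk <- runif(length(pid))
    data.frame(patient_id = pid, block_index = blk, risk = risk,
               outcome = rbinom(length(pid), 1, plogis(2.5 * (risk - 0.5))))
  }
  truth <- stratified_weighted_auroc(gen(20000, 99))$auroc

  p40 <- gen(40, 1)
  stat <- function(p) stratified_weighted_auroc(p)$auroc
  ci_a <- bootstrap_ci(p40, stat, n_boot = 300, seed = 3)$ci
  ci_b <- bootstrap_ci(p40, stat, n_boot = 600, seed = 3)$ci
  expect_lt(max(abs(ci_a - ci_b)), 0.06)  # Monte-Carlo stability

  hits <- 0; reps <- 120
  for (r in seq_len(reps)) {
    ci <- tryCatch(bootstrap_ci(gen(40, 100 + r), stat,
                                n_boot = 200, seed = r)$ci,
                   error = function(e) NULL)
    if (is.null(ci)) { reps <- reps - 1; next }
    if (truth >= ci[1] && truth <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.85)  # close to nominal 95% at n = 40 patients
})

test_that("count-based quasi-Poisson RR recovers known measurement-rate ratios", {
  with_seed_local(7, {
    doubled <- rate_cohort(n = 2000, rr = 2)
    null <- rate_cohort(n = 2000, rr = 1)
  })
  r2 <- count_rr(doubled, "lab1")
  expect_equal(r2$rr, 2, tolerance = 0.1)
  r1 <- count_rr(null, "lab1")
  expect_equal(r1$rr, 1, tolerance = 0.1)
  expect_true(r1$ci[1] <= 1 && 1 <= r1$ci[2])
  expect_true(r2$ci[1] <= r2$rr && r2$rr <= r2$ci[2])
})

test_that("ever/never sandwich-Poisson RR recovers known ever-observed ratios", {
  with_seed_local(8, {
    doubled <- rate_cohort(n = 3000, p_obs_control = 0.2, rr = 2, ever = TRUE)
    null <- rate_cohort(n = 3000, p_obs_control = 0.3, rr = 1, ever = TRUE)
  })
  r2 <- ever_never_rr(doubled, "lab1")
  expect_equal(r2$rr, 2, tolerance = 0.12)
  r1 <- ever_never_rr(null, "lab1")
  expect_equal(r1$rr, 1, tolerance = 0.1)

  none <- rate_cohort(n = 50, p_obs_control = 0, rr = 1, ever = TRUE)
  expect_error(ever_never_rr(none, "lab1"), "never observed")
})

test_that("SMD matches closed forms for continuous, binary and identical groups", {
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
  # means one pooled SD apart
  a <- c(0, 1, 2); b <- a + 1
  expect_equal(smd(a, b), 1)
  # binary closed form at 50% vs 60%
  x <- rep(c("y", "n"), c(50, 50))
  y <- rep(c("y", "n"), c(60, 40))
  expect_equal(smd(x, y),
               abs(0.5 - 0.6) / sqrt((0.5 * 0.5 + 0.6 * 0.4) / 2))
  expect_error(smd(c(1, 1), c(2, 2)), "zero pooled SD")
  tab <- smd_table(small_cohort(200, seed = 3))
  expect_true(all(tab$smd >= 0))
})
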