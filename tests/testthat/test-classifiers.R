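# small cross-sectional task with a known signal, built on the toy lab panel
toy_task <- function(n = 600, seed = 21, xor = FALSE) {
  set.seed(seed)
  l1 <- rnorm(n); l2 <- rnorm(n)
  eta <- if (xor) 3 * sign(l1 * l2) else 1.5 * l1 - 1.5 * l2
  coh <- toy_cohort(list(l1 = l1, l2 = l2), patient_id = seq_len(n))
  coh$outcome <- rbinom(n, 1, plogis(eta))
  coh$age <- round(runif(n, 20, 90))
  coh$sex <- factor(sample(c("Female", "Male"), n, replace = TRUE))
  coh
}

test_that("the lasso collapses to the base rate at huge penalty and separates easy data", {
  coh <- toy_task(seed = 2)
  m_big <- fit_lasso_logistic(coh, labs = toy_labs(),
                              lambda = c(1e3, 9e2), seed = 1)
  p_big <- predict(m_big, coh)
  expect_lt(diff(range(p_big)), 1e-6)
  expect_equal(mean(p_big), mean(coh$outcome), tolerance = 0.02)

  sep <- toy_task(seed = 3)
  sep$outcome <- as.integer(sep$l1 > sep$l2)  # linearly separable
  m <- fit_lasso_logistic(sep, labs = toy_labs(), seed = 1)
  expect_gt(auroc(predict(m, sep), sep$outcome), 0.99)
})

test_that("permuted labels give a cross-validated AUROC near one half", {
  coh <- toy_task(seed = 4)
  coh$outcome <- with_seed_local(5, sample(coh$outcome))
  m <- fit_lasso_logistic(coh, labs = toy_labs(), seed = 1)
  expect_lt(abs(auroc(predict(m, toy_task(seed = 6)), toy_task(seed = 6)$outcome) - 0.5),
            0.12)
})

test_that("the MLP rejects empty architectures and learns XOR structure", {
  expect_error(classifier_config(hidden = integer(0)), "hidden layer")
  expect_error(classifier_config(hidden = 0L), "hidden layer")

  xor <- toy_task(n = 1200, seed = 7, xor = TRUE)
  m <- fit_mlp(xor, labs = toy_labs(), lab_mode = "numeric",
               config = classifier_config(hidden = c(16L, 8L), epochs = 60L,
                                          lr = 5e-3, dropout = 0, seed = 2))
  held <- toy_task(n = 800, seed = 8, xor = TRUE)
  expect_gt(auroc(predict(m, held), held$outcome), 0.9)

  # a linear model cannot crack XOR
  lin <- fit_lasso_logistic(xor, labs = toy_labs(), seed = 1)
  expect_lt(auroc(predict(lin, held), held$outcome), 0.65)
})

test_that("identical seed and config reproduce identical risks", {
  coh <- toy_task(seed = 9)
  cfg <- classifier_config(hidden = 8L, epochs = 5L, seed = 11)
  m1 <- fit_mlp(coh, labs = toy_labs(), config = cfg)
  m2 <- fit_mlp(coh, labs = toy_labs(), config = cfg)
  expect_identical(predict(m1, coh), predict(m2, coh))
})

test_that("LSTM risks are causal and sequences beyond 14 blocks are rejected", {
  coh <- small_cohort(150, seed = 15)
  m <- fit_lstm(coh, lab_mode = "embedding",
                config = classifier_config(hidden = 6L, epochs = 2L,
                                           seed = 1))
  # modify a later block of a multi-block patient; earlier risks unchanged
  lens <- table(coh$patient_id)
  pid <- as.integer(names(lens)[lens >= 3][1])
  rows <- which(coh$patient_id == pid)
  mod <- coh
  mod$bun[rows[3]] <- 99
  mod$outcome[rows[3]] <- 1 - mod$outcome[rows[3]]
  r0 <- predict(m, coh)[rows]
  r1 <- predict(m, mod)[rows]
  expect_equal(r1[1:2], r0[1:2])

  long <- coh
  long$block_index[nrow(long)] <- 20L
  expect_error(predict(m, long), "max_blocks")
})

test_that("an LSTM exploits a two-block-lag signal that a cross-sectional MLP cannot", {
  set.seed(31)
  n <- 500; Tn <- 6
  pid <- rep(seq_len(n), each = Tn)
  x <- rnorm(n * Tn)
  coh <- toy_cohort(list(l1 = x, l2 = rnorm(n * Tn)), patient_id = pid)
  # label at block t depends on l1 at block t-2 only
  lag2 <- ave(x, pid, FUN = function(v) c(0, 0, v[seq_len(length(v) - 2)]))
  coh$outcome <- rbinom(n * Tn, 1, plogis(3 * lag2))
  coh$age <- round(runif(n * Tn, 20, 90))
  coh$sex <- factor(sample(c("Female", "Male"), n * Tn, replace = TRUE))
  split <- split_patients(coh, 0.7, seed = 2)

  cfg_l <- classifier_config(hidden = 12L, epochs = 40L, lr = 5e-3,
                             batch_size = 64L, seed = 3)
  lstm <- fit_lstm(split$train, labs = toy_labs(), config = cfg_l,
                   max_blocks = 6L)
  mlp <- fit_mlp(split$train, labs = toy_labs(),
                 config = classifier_config(hidden = c(12L, 6L), epochs = 30L,
                                            lr = 3e-3, dropout = 0, seed = 3))
  a_lstm <- auroc(predict(lstm, split$test), split$test$outcome)
  a_mlp <- auroc(predict(mlp, split$test), split$test$outcome)
  expect_gt(a_lstm, a_mlp + 0.05)
  expect_lt(abs(a_mlp - 0.5), 0.08)  # cross-sectional model is blind to the lag
})

test_that("successive halving follows the budget schedule and returns the best survivor", {
  # deterministic surrogate: loss falls with epochs, offset by candidate rank
  losses <- function(cand, epochs) cand$quality + 1 / epochs
  cands <- lapply(c(0.5, 0.1, 0.3, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9),
                  function(q) list(quality = q))
  out <- tune(cands, losses, R = 9, eta = 3)
  expect_equal(out$best$quality, 0.1)
  rounds <- split(out$log, out$log$round)
  expect_equal(vapply(rounds, nrow, 0L), c(`1` = 9L, `2` = 3L, `3` = 1L))
  expect_equal(unique(out$log$epochs[out$log$round == 1]), 1)
  expect_equal(unique(out$log$epochs[out$log$round == 2]), 3)
  expect_equal(unique(out$log$epochs[out$log$round == 3]), 9)
  # monotone: the winner beats every eliminated candidate at equal budget
  for (r in rounds) expect_lte(min(r$loss), min(rounds[[1]]$loss))

  single <- tune(cands[1], losses, R = 9, eta = 3)
  expect_equal(single$best$quality, 0.5)
  expect_equal(single$log$epochs, 9)

  # budget too small for a halving round: random-search fallback, logged
  fb <- tune(cands, losses, R = 2, eta = 3)
  expect_true(any(grepl("fallback", fb$log$note)))
  expect_equal(fb$best$quality, 0.1)

  # ties broken by candidate order
  tie <- tune(list(list(quality = 0.2), list(quality = 0.2)),
              losses, R = 3, eta = 3)
  expect_equal(tie$best_index, 1L)
})

test_that("label depending only on the current block: LSTM matches MLP within noise", {
  set.seed(41)
  n <- 400; Tn <- 5
  pid <- rep(seq_len(n), each = Tn)
  x <- rnorm(n * Tn)
  coh <- toy_cohort(list(l1 = x, l2 = rnorm(n * Tn)), patient_id = pid)
  coh$outcome <- rbinom(n * Tn, 1, plogis(2 * x))
  coh$age <- round(runif(n * Tn, 20, 90))
  coh$sex <- factor(sample(c("Female", "Male"), n * Tn, replace = TRUE))
  split <- split_patients(coh, 0.7, seed = 1)
  lstm <- fit_lstm(split$train, labs = toy_labs(),
                   config = classifier_config(hidden = 8L, epochs = 30L,
                                              lr = 5e-3, batch_size = 64L,
                                              seed = 2), max_blocks = 5L)
  mlp <- fit_mlp(split$train, labs = toy_labs(),
                 config = classifier_config(hidden = 8L, epochs = 30L,
                                            lr = 3e-3, dropout = 0, seed = 2))
  a_lstm <- auroc(predict(lstm, split$test), split$test$outcome)
  a_mlp <- auroc(predict(mlp, split$test), split$test$outcome)
  expect_lt(abs(a_lstm - a_mlp), 0.05)
})
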