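test_that("mean imputation uses observed means and preserves them exactly", {
  coh <- toy_cohort(list(l1 = c(2, 4, 6, NA), l2 = c(1, 1, 1, 1)))
  st <- fit_mean_imputer(coh, toy_labs())
  expect_equal(unname(st$means["l1"]), 4)
  expect_equal(unname(st$n_obs["l1"]), 3)
  out <- apply_imputer(st, coh)
  expect_equal(out$l1, c(2, 4, 6, 4))
  expect_equal(out$l2, coh$l2)                       # fully observed untouched
  expect_equal(mean(out$l1), mean(coh$l1, na.rm = TRUE))  # mean preserved

  never <- toy_cohort(list(l1 = c(NA, NA), l2 = c(1, 2)))
  expect_error(fit_mean_imputer(never, toy_labs()), "l1")
})

test_that("normal-value imputation fills normal-range midpoints and nothing else", {
  labs <- lab_config()
  coh <- small_cohort(100, seed = 4)
  out <- normal_value_impute(labs, coh)
  expect_equal(unique(out$bun[is.na(coh$bun)]), 13.5)
  expect_equal(unique(out$potassium[is.na(coh$potassium)]), 4.25)
  expect_equal(unique(out$troponin[is.na(coh$troponin)]), 0.05)
  obs <- !is.na(coh$sodium)
  expect_identical(out$sodium[obs], coh$sodium[obs])
})

test_that("categorical encoding maps the four levels by the normal-range cut points", {
  labs <- lab_config()
  coh <- toy_cohort(list(potassium = c(3.0, 4.0, 6.0, NA),
                         sodium = c(140, NA, 130, 150),
                         lactate = c(NA, 1.0, 5.0, 0.1)))
  out <- categorical_encode(labs, coh)
  expect_equal(as.character(out$potassium), c("low", "normal", "high", "unknown"))
  expect_equal(as.character(out$sodium), c("normal", "unknown", "low", "high"))
  expect_equal(as.character(out$lactate), c("unknown", "normal", "high", "low"))
  expect_equal(levels(out$potassium), c("unknown", "low", "normal", "high"))
})

test_that("LOCF fills forward within patients only, leaving leading gaps", {
  coh <- toy_cohort(list(l1 = c(5, NA, NA, 7, NA), l2 = c(NA, NA, 3, NA, NA)))
  out <- locf_augment(coh, toy_labs())
  expect_equal(out$l1, c(5, 5, 5, 7, 7))
  expect_equal(out$l2, c(NA, NA, 3, 3, 3))

  two <- toy_cohort(list(l1 = c(9, NA, NA, NA)),
                    patient_id = c(1L, 1L, 2L, 2L))
  out2 <- locf_augment(two, toy_labs())
  expect_equal(out2$l1, c(9, 9, NA, NA))   # never crosses patients

  bad <- toy_cohort(list(l1 = c(1, 2)))
  bad$block_index <- c(1L, 0L)
  expect_error(locf_augment(bad, toy_labs()), "ordered")
})

test_that("LOCF fill is monotone: missing at t implies missing at every earlier block", {
  coh <- small_cohort(150, seed = 6)
  out <- locf_augment(coh)
  for (l in cohort_lab_names(out)) {
    by_pat <- split(is.na(out[[l]]), out$patient_id)
    expect_true(all(vapply(by_pat, function(m) all(diff(m) <= 0), TRUE)))
  }
})

test_that("pmm imputes only observed training values and is deterministic", {
  coh <- small_cohort(150, seed = 7)
  st <- fit_imputer(coh, "pmm", n_iterations = 3, seed = 2)
  out <- apply_imputer(st, coh)
  for (l in cohort_lab_names(coh)) {
    expect_false(anyNA(out[[l]]))
    mis <- is.na(coh[[l]])
    expect_true(all(out[[l]][mis] %in% coh[[l]][!mis]))
    expect_identical(out[[l]][!mis], coh[[l]][!mis])
  }
  expect_identical(apply_imputer(st, coh), out)

  few <- toy_cohort(list(l1 = c(1, NA, NA), l2 = c(1, 2, 3)))
  expect_error(fit_imputer(few, "pmm", labs = toy_labs()), "l1")
  expect_error(fit_imputer(coh, "pmm", n_iterations = 0), "n_iterations")
})

test_that("pmm recovers a known linear conditional mean under MAR", {
  # l2 = 2 * l1 + e, missing where l1 is large (MAR given l1)
  set.seed(11)
  n <- 1500
  l1 <- rnorm(n)
  l2 <- 2 * l1 + rnorm(n, 0, 0.5)
  mis <- stats::runif(n) < stats::plogis(2 * l1)
  coh <- toy_cohort(list(l1 = l1, l2 = ifelse(mis, NA, l2)),
                    patient_id = seq_len(n))
  st <- fit_imputer(coh, "pmm", labs = toy_labs(), n_iterations = 5, seed = 3)
  out <- apply_imputer(st, coh)
  truth <- mean(2 * l1[mis])                   # analytic conditional mean
  mc_se <- stats::sd(l2[!mis]) / sqrt(sum(mis))
  expect_lt(abs(mean(out$l2[mis]) - truth), 4 * mc_se + 0.1)
})

test_that("all strategies preserve observed values and complete the labs", {
  coh <- small_cohort(120, seed = 9)
  test <- small_cohort(120, seed = 10)
  for (strat in c("mean", "normal_value", "categorical", "pmm")) {
    for (locf in c(FALSE, TRUE)) {
      st <- fit_imputer(coh, strat, locf = locf, n_iterations = 2)
      out <- apply_imputer(st, test)
      for (l in cohort_lab_names(test)) {
        obs <- !is.na(test[[l]])
        if (strat == "categorical") {
          expect_false(anyNA(out[[l]]))
          if (!locf) {
            expect_equal(sum(out[[l]] == "unknown"), sum(is.na(test[[l]])))
          }
        } else {
          expect_false(anyNA(out[[l]]))
          expect_identical(out[[l]][obs], test[[l]][obs])
        }
      }
    }
  }
})

test_that("completed-output strategies are idempotent", {
  coh <- small_cohort(100, seed = 12)
  for (strat in c("mean", "normal_value", "pmm")) {
    st <- fit_imputer(coh, strat, n_iterations = 2)
    once <- apply_imputer(st, coh)
    twice <- apply_imputer(st, once)
    expect_identical(twice, once)
  }
})

test_that("imputer states survive a JSON round-trip", {
  coh <- small_cohort(100, seed = 13)
  test <- small_cohort(80, seed = 14)
  for (strat in c("mean", "normal_value", "pmm")) {
    st <- fit_imputer(coh, strat, n_iterations = 2, seed = 5)
    path <- tempfile(fileext = ".json")
    imputer_to_json(st, path)
    st2 <- imputer_from_json(path)
    expect_equal(apply_imputer(st2, test), apply_imputer(st, test))
  }
})

test_that("plausibility QC counts out-of-limit values without altering them", {
  coh <- toy_cohort(list(potassium = c(20, 4, NA), sodium = c(80, 140, 150)))
  qc <- qc_plausibility(coh)
  expect_equal(qc$n_above_limit[qc$lab == "potassium"], 1)
  expect_equal(qc$n_below_limit[qc$lab == "sodium"], 1)
})
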