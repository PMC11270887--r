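# Shared fixtures, all generated in code.

with_seed_local <- informiss:::with_seed

# small simulated cohort, memoised per (n, seed, mechanism)
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(n = 300, seed = 1, mechanism = "nmar") {
  key <- paste(n, seed, mechanism, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(
      cohort_config(n_patients = n, seed = seed, mechanism = mechanism))
  }
  .cohort_cache[[key]]
}

# a hand-built two-lab config for synthetic imputer tests
toy_labs <- function() {
  labs <- data.frame(
    name = c("l1", "l2"),
    label = c("L1", "L2"),
    regular = c(TRUE, TRUE),
    lower_limit = c(-100, -100), lower_normal = c(-1, -1),
    upper_normal = c(1, 1), upper_limit = c(100, 100),
    severity_direction = c(1, 1),
    stringsAsFactors = FALSE)
  labs$normal_value <- 0
  class(labs) <- c("lab_config", "data.frame")
  labs
}

# longitudinal toy cohort with explicit values (one row per patient-block)
toy_cohort <- function(values, patient_id = NULL, outcome = NULL) {
  # values: list of per-lab numeric vectors (NA = missing)
  n <- length(values[[1]])
  if (is.null(patient_id)) patient_id <- rep(1L, n)
  d <- data.frame(patient_id = patient_id,
                  block_index = unlist(lapply(rle(patient_id)$lengths,
                                              function(k) seq_len(k) - 1L)))
  for (nm in names(values)) d[[nm]] <- values[[nm]]
  d$outcome <- if (is.null(outcome)) 0L else outcome
  class(d) <- c("cohort_table", "data.frame")
  d
}

# exhaustive pairwise AUROC oracle: all positive-negative pairs, ties half
auroc_oracle <- function(risk, outcome) {
  pos <- risk[outcome == 1]
  neg <- risk[outcome == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# synthetic per-patient observation cohort with a known case/control
# measurement-rate ratio (used by the RR estimator recovery suites)
rate_cohort <- function(n = 300, p_case = 0.3, p_obs_control = 0.35,
                        rr = 2, ever = FALSE) {
  case <- stats::runif(n) < p_case
  los <- sample(4:12, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    k <- los[i]
    if (ever) {
      p <- min(p_obs_control * rr^case[i], 0.99)
      lab <- rep(NA_real_, k)
      if (stats::runif(1) < p) lab[sample.int(k, 1)] <- 1
    } else {
      p <- min(p_obs_control * rr^case[i], 0.99)
      lab <- ifelse(stats::runif(k) < p, 1, NA_real_)
    }
    data.frame(patient_id = i, block_index = seq_len(k) - 1L, lab1 = lab,
               outcome = c(rep(0L, k - 1L), as.integer(case[i])))
  })
  d <- do.call(rbind, rows)
  class(d) <- c("cohort_table", "data.frame")
  d
}
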