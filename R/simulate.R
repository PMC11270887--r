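#' Simulate a longitudinal inpatient cohort
#'
#' Generates a block-level cohort table: one row per patient per 12-hour
#' block, with demographics, twelve lab columns observed through the
#' configured missingness mechanism (missing entries are \code{NA}), and a
#' binary deterioration outcome. A latent severity process
#' \eqn{s_t = b + \rho (s_{t-1} - b) + \epsilon_t} (stationary, unit marginal
#' SD; \eqn{b} a small demographic baseline shift) is the shared cause of lab
#' abnormality, of measurement under NMAR, and of deterioration. Each lab's
#' true value is the midpoint of its normal range plus a severity-driven
#' abnormality plus noise, truncated at the plausibility limits. One-sided
#' labs (e.g. lactate, troponin) deviate linearly in severity toward their
#' abnormal tail; clinically two-sided labs (e.g. potassium, sodium, pH)
#' deviate toward a patient-specific tail — hypo- or hyper- — and only while
#' severity is above its typical level, giving the U-shaped lab-risk
#' relations characteristic of laboratory data. Each block the
#' patient can deteriorate (probability logistic in severity; ends the stay,
#' outcome recorded on that block) or be discharged (constant hazard);
#' otherwise the stay is censored after \code{max_blocks} blocks (7 days).
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data frame of class \code{cohort_table}, ordered by
#'   \code{patient_id} then \code{block_index} (0-based, contiguous), with
#'   demographic columns (\code{age}, \code{sex}, \code{race},
#'   \code{admission_type}), one column per lab (\code{NA} = missing),
#'   \code{outcome} (1 only on a deteriorating patient's final block), and —
#'   when \code{config$debug_severity} — the latent \code{severity}.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 50, seed = 1))
#' max(table(coh$patient_id)) <= 14
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labs <- config$labs
  mech <- config$mechanism
  n <- config$n_patients
  p <- nrow(labs)
  halfw <- (labs$upper_normal - labs$lower_normal) / 2
  mid <- (labs$upper_normal + labs$lower_normal) / 2
  loading <- labs$severity_direction * config$lab_loading_scale * halfw
  noise_sd <- config$lab_noise_scale * halfw

  set.seed(config$seed)

  two_sided <- if ("two_sided" %in% names(labs)) labs$two_sided else
    rep(FALSE, p)

  demo <- simulate_demographics(n)
  base_sev <- 0.01 * (demo$age - 58) +
    0.15 * (demo$sex == "Male") +
    c(Elective = -0.10, Emergency = 0.10, `Trauma Center` = 0.20,
      Urgent = 0)[as.character(demo$admission_type)]
  names(base_sev) <- NULL

  stat_sd <- config$severity_innovation_sd / sqrt(1 - config$severity_rho^2)

  active <- seq_len(n)
  sev <- base_sev + stats::rnorm(n, 0, stat_sd)
  # patient-specific abnormality direction for clinically two-sided labs
  # (e.g. hypo- vs hyperkalaemia): both extremes signal severity
  lab_dir <- matrix(rep(labs$severity_direction, each = n), n, p)
  if (any(two_sided)) {
    lab_dir[, two_sided] <- sample(c(-1, 1), n * sum(two_sided),
                                   replace = TRUE)
  }
  last_z <- matrix(0, n, p)  # standardised last observed abnormality (MAR)
  blocks <- vector("list", config$max_blocks)

  for (t in seq_len(config$max_blocks) - 1L) {
    na <- length(active)
    if (na == 0) break
    s <- sev[active]

    sev_term <- matrix(s, na, p)
    sev_term[, two_sided] <- pmax(sev_term[, two_sided, drop = FALSE], 0)
    dev <- lab_dir[active, , drop = FALSE] * sev_term *
      matrix(abs(loading), na, p, byrow = TRUE)
    true_vals <- matrix(mid, na, p, byrow = TRUE) + dev +
      matrix(stats::rnorm(na * p), na, p) %*% diag(noise_sd, p)
    true_vals <- pmin(pmax(true_vals,
                           matrix(labs$lower_limit, na, p, byrow = TRUE)),
                      matrix(labs$upper_limit, na, p, byrow = TRUE))

    eta <- matrix(mech$base_logodds, na, p, byrow = TRUE)
    if (mech$mechanism == "nmar") {
      eta <- eta + s %o% mech$severity_coef
    } else if (mech$mechanism == "mar") {
      eta <- eta + last_z[active, , drop = FALSE] %*% diag(mech$lag_coef, p)
    }
    observed <- matrix(stats::runif(na * p), na, p) < stats::plogis(eta)
    vals <- true_vals
    vals[!observed] <- NA_real_

    # MAR covariate: how abnormal was the last observed value (either tail)
    zc <- abs(sweep(sweep(true_vals, 2, mid), 2, halfw, "/"))
    lz <- last_z[active, , drop = FALSE]
    lz[observed] <- zc[observed]
    last_z[active, ] <- lz

    p_event <- stats::plogis(config$event_intercept + config$event_slope * s)
    event <- stats::runif(na) < p_event
    discharge <- !event & stats::runif(na) < config$discharge_hazard

    block <- data.frame(patient_id = active,
                        block_index = t,
                        stringsAsFactors = FALSE)
    block <- cbind(block, demo[active, , drop = FALSE])
    colnames(vals) <- labs$name
    block <- cbind(block, as.data.frame(vals))
    block$outcome <- as.integer(event)
    if (config$debug_severity) block$severity <- s
    rownames(block) <- NULL
    blocks[[t + 1L]] <- block

    keep <- !(event | discharge) & (t < config$max_blocks - 1L)
    sev_next <- base_sev[active] +
      config$severity_rho * (s - base_sev[active]) +
      stats::rnorm(na, 0, config$severity_innovation_sd)
    sev[active] <- sev_next
    active <- active[keep]
  }

  cohort <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  cohort <- cohort[order(cohort$patient_id, cohort$block_index), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "lab_names") <- labs$name
  cohort
}

simulate_demographics <- function(n) {
  race_levels <- c("American Indian or Alaskan Native", "Asian",
                   "Black or African American", "Caucasian/White",
                   "Missing", "Other")
  adm_levels <- c("Elective", "Emergency", "Trauma Center", "Urgent")
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 57, 18)), 18), 100),
    sex = factor(ifelse(stats::runif(n) < 0.535, "Female", "Male"),
                 levels = c("Female", "Male")),
    race = factor(sample(race_levels, n, replace = TRUE,
                         prob = c(0.006, 0.017, 0.296, 0.622, 0.016, 0.043)),
                  levels = race_levels),
    admission_type = factor(sample(adm_levels, n, replace = TRUE,
                                   prob = c(0.300, 0.437, 0.001, 0.262)),
                            levels = adm_levels),
    stringsAsFactors = FALSE)
}

#' Lab columns of a cohort table
#'
#' @param cohort A cohort table (any data frame with lab columns).
#' @param labs A \code{\link{lab_config}}; only labs present as columns are
#'   returned.
#' @return Character vector of lab column names present in \code{cohort}.
#' @export
cohort_lab_names <- function(cohort, labs = lab_config()) {
  intersect(labs$name, names(cohort))
}

#' Summarise a cohort table
#'
#' Computes the descriptive statistics used to characterise a cohort and its
#' missingness: cohort size, event rates at the patient and block level,
#' blocks per patient, per-lab block-level missingness, and the case-versus-
#' control observation comparison (per-patient observed counts for every lab,
#' ever-observed rates for every lab).
#'
#' @param cohort A \code{cohort_table}.
#' @param labs A \code{\link{lab_config}}.
#' @return A list of class \code{cohort_summary}: \code{n_patients},
#'   \code{n_blocks}, \code{patient_event_rate}, \code{block_event_rate},
#'   \code{blocks_median}, \code{blocks_iqr}, and a per-lab data frame
#'   \code{lab_summary} with missingness rate and case/control ever-observed
#'   rates.
#' @export
summarize_cohort <- function(cohort, labs = lab_config()) {
  if (nrow(cohort) == 0) stop("empty cohort")
  lnames <- cohort_lab_names(cohort, labs)
  per_pat <- stats::aggregate(cohort$outcome,
                              by = list(patient_id = cohort$patient_id),
                              FUN = max)
  blocks_per <- table(cohort$patient_id)
  case_ids <- per_pat$patient_id[per_pat$x == 1]
  is_case_row <- cohort$patient_id %in% case_ids

  lab_summary <- do.call(rbind, lapply(lnames, function(ln) {
    miss <- is.na(cohort[[ln]])
    obs_by_pat <- tapply(!miss, cohort$patient_id, any)
    data.frame(
      lab = ln,
      regular = labs$regular[match(ln, labs$name)],
      missingness_rate = mean(miss),
      case_ever_observed = mean(obs_by_pat[as.character(case_ids)]),
      control_ever_observed = mean(obs_by_pat[setdiff(names(obs_by_pat),
                                                      as.character(case_ids))]),
      case_block_observed = mean(!miss[is_case_row]),
      control_block_observed = mean(!miss[!is_case_row]),
      stringsAsFactors = FALSE)
  }))
  rownames(lab_summary) <- NULL

  structure(list(
    n_patients = nrow(per_pat),
    n_blocks = nrow(cohort),
    patient_event_rate = mean(per_pat$x),
    block_event_rate = mean(cohort$outcome),
    blocks_median = stats::median(as.integer(blocks_per)),
    blocks_iqr = unname(stats::quantile(as.integer(blocks_per),
                                        c(0.25, 0.75), type = 1)),
    lab_summary = lab_summary), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d observation blocks\n",
              x$n_patients, x$n_blocks))
  cat(sprintf("Patient-level event rate: %.1f%%; block-level: %.2f%%\n",
              100 * x$patient_event_rate, 100 * x$block_event_rate))
  cat(sprintf("Blocks per patient: median %d (IQR %d-%d)\n",
              x$blocks_median, x$blocks_iqr[1], x$blocks_iqr[2]))
  reg <- x$lab_summary$regular
  cat(sprintf("Mean block-level missingness: regular labs %.1f%%, informative labs %.1f%%\n",
              100 * mean(x$lab_summary$missingness_rate[reg]),
              100 * mean(x$lab_summary$missingness_rate[!reg])))
  invisible(x)
}

#' Read/write a cohort as CSV with a JSON config sidecar
#'
#' Missing lab values are encoded as empty cells. \code{write_cohort} also
#' writes \code{<path>.config.json} recording the generating configuration
#' when one is supplied.
#'
#' @param cohort A \code{cohort_table}.
#' @param path CSV path.
#' @param config Optional \code{\link{cohort_config}} to record alongside.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    cfg <- config
    cfg$labs <- as.data.frame(unclass(cfg$labs))
    cfg$mechanism <- unclass(cfg$mechanism)
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @param labs A \code{\link{lab_config}} used to type the lab columns.
#' @return \code{read_cohort}: a \code{cohort_table}.
#' @export
read_cohort <- function(path, labs = lab_config()) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c("sex", "race", "admission_type")) {
    if (v %in% names(cohort)) cohort[[v]] <- factor(cohort[[v]])
  }
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "lab_names") <- cohort_lab_names(cohort, labs)
  cohort
}
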