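#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive observation receives a
#' higher risk than a randomly chosen negative one, with ties counted half —
#' computed from midranks, which is exactly the normalised Mann-Whitney U.
#'
#' @param risk Numeric risks.
#' @param outcome Binary outcomes (0/1).
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(risk, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(risk, ties.method = "average")
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Length-of-stay-stratified weighted AUROC
#'
#' Stratifies the predictions by time since admission (the block index), so
#' that each patient contributes at most one observation per stratum and
#' observations are independent within strata; computes the AUROC per
#' stratum; and aggregates with weights equal to each stratum's share of the
#' observations in usable strata. Strata containing a single outcome class
#' carry no ranking information and are dropped, with the weights
#' renormalised over the remainder (the dropped strata are reported).
#'
#' @param preds A prediction set (\code{patient_id}, \code{block_index},
#'   \code{risk}, \code{outcome}), e.g. from \code{\link{prediction_set}}.
#' @param stratify_by \code{"block"} (default: time since admission) or
#'   \code{"patient_los"} (strata are each patient's total length of stay;
#'   the alternative reading, available for comparison but without the
#'   within-stratum independence rationale).
#' @return An \code{evaluation_report} list: \code{auroc} (aggregated),
#'   \code{strata} data frame (stratum, n, weight, auroc), \code{dropped}.
#' @export
stratified_weighted_auroc <- function(preds,
                                      stratify_by = c("block", "patient_los")) {
  stratify_by <- match.arg(stratify_by)
  stratum <- if (stratify_by == "block") {
    preds$block_index
  } else {
    los <- stats::ave(preds$block_index, preds$patient_id,
                      FUN = function(b) max(b) + 1L)
    los
  }
  groups <- split(seq_len(nrow(preds)), stratum)
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    y <- preds$outcome[idx]
    if (length(unique(y)) < 2) {
      return(data.frame(stratum = gname, n = length(idx), auroc = NA_real_))
    }
    data.frame(stratum = gname, n = length(idx),
               auroc = auroc(preds$risk[idx], y))
  })
  tab <- do.call(rbind, rows)
  usable <- !is.na(tab$auroc)
  if (!any(usable)) stop("no stratum contains both outcome classes")
  tab$weight <- ifelse(usable, tab$n / sum(tab$n[usable]), 0)
  agg <- sum(tab$weight[usable] * tab$auroc[usable])
  structure(list(auroc = agg,
                 strata = tab[usable, c("stratum", "n", "weight", "auroc")],
                 dropped = tab$stratum[!usable],
                 stratify_by = stratify_by),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Stratified weighted AUROC: %.3f (%d strata", x$auroc,
              nrow(x$strata)))
  if (length(x$dropped) > 0) {
    cat(sprintf(", %d dropped single-class", length(x$dropped)))
  }
  cat(")\n")
  if (!is.null(x$ci)) {
    cat(sprintf("95%% CI (basic bootstrap, %d resamples): (%.3f, %.3f)\n",
                x$n_boot, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Patient-level basic bootstrap confidence interval
#'
#' Resamples patients with replacement (all of a patient's blocks travel
#' together, respecting the intra-patient correlation), recomputes the
#' statistic on each resample, and returns the basic (reflected) interval
#' \eqn{(2\hat\theta - q_{0.975},\; 2\hat\theta - q_{0.025})} of the
#' replicate distribution. Replicates in which the statistic is undefined
#' (e.g. a single outcome class) are dropped; more than 20% dropped is an
#' error.
#'
#' @param preds A prediction set.
#' @param statistic Function of a prediction set returning a scalar; default
#'   the stratified weighted AUROC.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Seed.
#' @param level Confidence level (default 0.95).
#' @return List with \code{estimate}, \code{ci} (low, high), \code{n_boot},
#'   \code{n_dropped}, \code{replicates}.
#' @export
bootstrap_ci <- function(preds,
                         statistic = function(p) stratified_weighted_auroc(p)$auroc,
                         n_boot = 500L, seed = 1L, level = 0.95) {
  patients <- unique(preds$patient_id)
  if (length(patients) < 2) stop("need >= 2 patients to bootstrap")
  if (n_boot < 200) stop("n_boot must be >= 200")
  theta <- statistic(preds)
  by_patient <- split(seq_len(nrow(preds)), preds$patient_id)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(patients, replace = TRUE)
      idx <- unlist(by_patient[as.character(take)], use.names = FALSE)
      res <- preds[idx, ]
      # resampled patients get fresh ids so duplicates stay distinct patients
      res$patient_id <- rep(seq_along(take),
                            lengths(by_patient[as.character(take)]))
      tryCatch(statistic(res), error = function(e) NA_real_)
    }, 0)
  })
  dropped <- sum(is.na(reps))
  if (dropped > 0.2 * n_boot) {
    stop("statistic undefined in >20% of bootstrap resamples")
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(reps[!is.na(reps)], c(1 - alpha, alpha), names = FALSE)
  list(estimate = theta, ci = c(2 * theta - q[1], 2 * theta - q[2]),
       n_boot = as.integer(n_boot), n_dropped = as.integer(dropped),
       replicates = reps)
}

#' Evaluate predictions: stratified AUROC with bootstrap CI
#'
#' Convenience wrapper combining \code{\link{stratified_weighted_auroc}} and
#' \code{\link{bootstrap_ci}}.
#'
#' @inheritParams bootstrap_ci
#' @param stratify_by Passed to \code{\link{stratified_weighted_auroc}}.
#' @return An \code{evaluation_report} with \code{ci} and \code{n_boot}.
#' @export
evaluate_predictions <- function(preds, n_boot = 500L, seed = 1L,
                                 stratify_by = "block") {
  rep_ <- stratified_weighted_auroc(preds, stratify_by = stratify_by)
  bs <- bootstrap_ci(preds,
                     statistic = function(p)
                       stratified_weighted_auroc(p, stratify_by)$auroc,
                     n_boot = n_boot, seed = seed)
  rep_$ci <- bs$ci
  rep_$n_boot <- bs$n_boot
  rep_$n_dropped <- bs$n_dropped
  rep_
}

#' Relative measurement rate for regularly collected labs
#'
#' Do deteriorating patients get measured more often? For a regularly
#' collected lab, regresses each patient's count of observed measurements on
#' case status with log length of stay (in blocks) as the offset, using
#' quasi-Poisson to absorb overdispersion (dispersion estimated by Pearson
#' chi-square / df). The exponentiated case coefficient is the relative rate;
#' the CI uses the dispersion-scaled standard errors.
#'
#' @param cohort A \code{cohort_table}.
#' @param lab Lab column name.
#' @return A \code{diagnostics_result} list: \code{lab}, \code{method},
#'   \code{rr}, \code{ci}, \code{n}.
#' @export
count_rr <- function(cohort, lab) {
  per <- patient_lab_frame(cohort, lab)
  if (all(per$count == 0)) stop("lab never observed")
  fit <- stats::glm(count ~ case, offset = log(los),
                    family = stats::quasipoisson(), data = per)
  sm <- summary(fit)$coefficients
  est <- sm["caseTRUE", "Estimate"]
  se <- sm["caseTRUE", "Std. Error"]
  structure(list(lab = lab, method = "count_quasipoisson_offset",
                 rr = exp(est),
                 ci = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 n = nrow(per)),
            class = "diagnostics_result")
}

#' Ever/never relative rate for informatively collected labs
#'
#' For an infrequently, informatively collected lab, regresses the binary
#' ever-observed indicator on case status, adjusting for length of stay, via
#' Poisson regression with a robust (HC0 sandwich) variance — the standard
#' device for obtaining valid relative-risk CIs from a binary outcome.
#'
#' @inheritParams count_rr
#' @return A \code{diagnostics_result}.
#' @export
ever_never_rr <- function(cohort, lab) {
  per <- patient_lab_frame(cohort, lab)
  per$ever <- as.integer(per$count > 0)
  if (all(per$ever == 0)) stop("lab never observed in either group")
  fit <- stats::glm(ever ~ case + los, family = stats::poisson(), data = per)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  est <- stats::coef(fit)["caseTRUE"]
  se <- sqrt(vc["caseTRUE", "caseTRUE"])
  structure(list(lab = lab, method = "evernever_sandwich_poisson",
                 rr = unname(exp(est)),
                 ci = unname(exp(est + c(-1, 1) * stats::qnorm(0.975) * se)),
                 n = nrow(per)),
            class = "diagnostics_result")
}

patient_lab_frame <- function(cohort, lab) {
  if (!lab %in% names(cohort)) stop("lab not found: ", lab)
  obs <- !is.na(cohort[[lab]])
  data.frame(
    count = as.integer(tapply(obs, cohort$patient_id, sum)),
    los = as.numeric(tapply(obs, cohort$patient_id, length)),
    case = as.vector(tapply(cohort$outcome, cohort$patient_id, max)) == 1)
}

#' @export
print.diagnostics_result <- function(x, ...) {
  cat(sprintf("%s [%s]: RR %.2f (95%% CI %.2f, %.2f), n = %d patients\n",
              x$lab, x$method, x$rr, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Standardised mean difference
#'
#' Scale-free between-group difference for cohort balance tables. For a
#' continuous variable, \eqn{|\bar x_a - \bar x_b| / s_p} with
#' \eqn{s_p = \sqrt{(s_a^2 + s_b^2)/2}}. For a categorical variable, the
#' multi-proportion Mahalanobis form over the first \eqn{K - 1} level
#' proportions (which reduces to the usual two-proportion formula for a
#' binary variable).
#'
#' @param a,b The variable's values in the two groups (numeric, or
#'   factor/character for categorical).
#' @return Non-negative SMD.
#' @export
smd <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) {
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    d <- abs(mean(a) - mean(b))
    if (sp == 0) {
      if (d > 0) stop("zero pooled SD with unequal means")
      return(0)
    }
    return(d / sp)
  }
  lev <- union(unique(as.character(a)), unique(as.character(b)))
  if (length(lev) < 2) return(0)
  pa <- as.vector(prop.table(table(factor(a, levels = lev))))[-1]
  pb <- as.vector(prop.table(table(factor(b, levels = lev))))[-1]
  S <- (outer_cov(pa) + outer_cov(pb)) / 2
  d <- pa - pb
  Sinv <- tryCatch(solve(S), error = function(e) MASS_ginv(S))
  sqrt(max(0, drop(t(d) %*% Sinv %*% d)))
}

outer_cov <- function(p) diag(p, length(p)) - p %o% p

# small Moore-Penrose fallback for singular multinomial covariances
MASS_ginv <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*%
    t(e$vectors[, pos, drop = FALSE])
}

#' Demographic balance table
#'
#' SMD between cases and controls for each demographic variable, computed at
#' the patient level.
#'
#' @param cohort A \code{cohort_table}.
#' @return Data frame with \code{variable} and \code{smd}.
#' @export
smd_table <- function(cohort) {
  first <- cohort[!duplicated(cohort$patient_id), ]
  case <- as.vector(tapply(cohort$outcome, cohort$patient_id, max)) == 1
  vars <- intersect(DEMO_COLS, names(first))
  do.call(rbind, lapply(vars, function(v) {
    data.frame(variable = v,
               smd = smd(first[[v]][case], first[[v]][!case]),
               stringsAsFactors = FALSE)
  }))
}
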