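#' Fit a missing-data strategy on training data
#'
#' Learns the state of one of the four fill-in strategies from a training
#' cohort, under a strict fit-on-train / apply-on-test contract: everything
#' data-dependent (per-lab means, conditional models, donor pools) is
#' estimated here and frozen, and \code{\link{apply_imputer}} never looks at
#' test-set values beyond the rows it is completing.
#'
#' Strategies:
#' \describe{
#'   \item{mean}{each missing entry of lab \eqn{j} is replaced by the mean of
#'     the observed training values of that lab (valid under MCAR only).}
#'   \item{pmm}{predictive mean matching inside a chained-equations loop:
#'     each lab is regressed on all other predictors (labs and demographics;
#'     the outcome is excluded), and a missing entry borrows the observed
#'     value of one of the \code{n_donors} training cases whose predicted
#'     means are closest (valid under MAR).}
#'   \item{normal_value}{each missing entry is replaced by the midpoint of
#'     the lab's clinical normal range — the assumption "not measured because
#'     presumed normal", a special NMAR strategy.}
#'   \item{categorical}{each lab becomes a four-level factor: "unknown"
#'     (missing), "low" (below the normal range), "normal", "high"; makes no
#'     mechanism assumption.}
#' }
#'
#' With \code{locf = TRUE}, application first carries each patient's last
#' observed raw value forward (never across patients), then the base strategy
#' resolves the leading entries that have no earlier observation; for the
#' categorical strategy the raw value is carried forward and then re-encoded,
#' so abnormality is re-evaluated against the same cut points.
#'
#' @param train Training \code{cohort_table}.
#' @param strategy One of "mean", "pmm", "normal_value", "categorical".
#' @param labs A \code{\link{lab_config}}.
#' @param locf Carry last observations forward before the base strategy.
#' @param n_iterations Chained-equation sweeps for pmm (default 10).
#' @param n_donors Donor-pool size for pmm (default 5).
#' @param seed Seed for pmm donor draws (stored, so application is
#'   deterministic).
#' @return An object of class \code{imputer_state}.
#' @seealso \code{\link{apply_imputer}}, \code{\link{locf_augment}},
#'   \code{\link{normal_value_impute}}, \code{\link{categorical_encode}}
#' @export
fit_imputer <- function(train,
                        strategy = c("mean", "pmm", "normal_value", "categorical"),
                        labs = lab_config(),
                        locf = FALSE,
                        n_iterations = 10L,
                        n_donors = 5L,
                        seed = 1L) {
  strategy <- match.arg(strategy)
  state <- switch(strategy,
    mean = fit_mean_imputer(train, labs),
    pmm = fit_pmm_imputer(train, labs, n_iterations = n_iterations,
                          n_donors = n_donors, seed = seed),
    normal_value = new_imputer("normal_value", labs,
                               normal_values = stats::setNames(labs$normal_value,
                                                               labs$name)),
    categorical = new_imputer("categorical", labs,
                              cuts = data.frame(lab = labs$name,
                                                lower = labs$lower_normal,
                                                upper = labs$upper_normal)))
  state$locf <- isTRUE(locf)
  state
}

new_imputer <- function(strategy, labs, ...) {
  structure(c(list(strategy = strategy, lab_names = labs$name, labs = labs,
                   locf = FALSE, notes = character(0)), list(...)),
            class = "imputer_state")
}

#' Mean imputer
#'
#' Estimates, for every lab \eqn{j}, the mean of its observed training values
#' \eqn{\hat x_j} and the observed count \eqn{N_{obs,j}}; a completed column
#' then has exactly the same mean as the observed part, at the cost of
#' distorted correlations.
#'
#' @inheritParams fit_imputer
#' @return An \code{imputer_state} with \code{means} and \code{n_obs}.
#' @export
fit_mean_imputer <- function(train, labs = lab_config()) {
  lnames <- check_lab_schema(train, labs)
  means <- vapply(lnames, function(l) mean(train[[l]], na.rm = TRUE), 0)
  n_obs <- vapply(lnames, function(l) sum(!is.na(train[[l]])), 0L)
  never <- lnames[n_obs == 0]
  if (length(never) > 0) {
    stop("lab(s) never observed in training data: ",
         paste(never, collapse = ", "))
  }
  st <- new_imputer("mean", labs)
  st$means <- means
  st$n_obs <- n_obs
  st
}

#' Predictive-mean-matching imputer (chained equations)
#'
#' Runs a chained-equations loop: missing entries are initialised by random
#' draws from each lab's observed values, then for \code{n_iterations} sweeps
#' each lab with missingness is linearly regressed on all other predictors
#' (the other labs, as currently completed, plus age, sex, race and admission
#' type; the outcome is excluded) and its missing entries are refilled by
#' drawing from the \code{n_donors} observed training cases with the closest
#' predicted means. After the final sweep the per-lab coefficients and donor
#' pools (observed value + predicted mean) are frozen for test-time use.
#' A rank-deficient conditional model falls back to marginal donor draws for
#' that lab and is recorded in \code{notes}.
#'
#' @inheritParams fit_imputer
#' @return An \code{imputer_state} with per-lab \code{models} (coefficients,
#'   donor values, donor predicted means).
#' @export
fit_pmm_imputer <- function(train, labs = lab_config(), n_iterations = 10L,
                            n_donors = 5L, seed = 1L) {
  lnames <- check_lab_schema(train, labs)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  too_few <- lnames[vapply(lnames, function(l) sum(!is.na(train[[l]])), 0L) < 2]
  if (length(too_few) > 0) {
    stop("pmm requires >= 2 observed values per lab; offending: ",
         paste(too_few, collapse = ", "))
  }

  X <- as.matrix(train[, lnames, drop = FALSE])
  M <- is.na(X)
  demo <- demographic_design(train)
  notes <- character(0)

  with_seed(seed, {
    # initialise missings with random observed draws
    for (j in seq_along(lnames)) {
      if (any(M[, j])) {
        X[M[, j], j] <- sample(X[!M[, j], j], sum(M[, j]), replace = TRUE)
      }
    }
    models <- vector("list", length(lnames))
    names(models) <- lnames
    for (iter in seq_len(n_iterations)) {
      for (j in seq_along(lnames)) {
        mis <- M[, j]
        design <- cbind(1, X[, -j, drop = FALSE], demo)
        fit <- tryCatch(stats::lm.fit(design[!mis, , drop = FALSE], X[!mis, j]),
                        error = function(e) NULL)
        if (is.null(fit) || all(is.na(fit$coefficients))) {
          coefs <- NULL
          eta <- rep(mean(X[!mis, j]), nrow(X))
          if (iter == n_iterations) {
            notes <- c(notes, paste0("marginal donor fallback for ", lnames[j]))
          }
        } else {
          coefs <- fit$coefficients
          if (anyNA(coefs)) {
            coefs[is.na(coefs)] <- 0  # aliased columns dropped
            if (iter == n_iterations) {
              notes <- c(notes, paste0("rank-deficient model for ", lnames[j]))
            }
          }
          eta <- drop(design %*% coefs)
        }
        if (any(mis)) {
          X[mis, j] <- pmm_draw(eta[mis], X[!mis, j], eta[!mis], n_donors)
        }
        if (iter == n_iterations) {
          models[[j]] <- list(coefficients = coefs,
                              donor_values = X[!mis, j],
                              donor_eta = eta[!mis])
        }
      }
    }
  })

  st <- new_imputer("pmm", labs)
  st$models <- models
  st$n_iterations <- as.integer(n_iterations)
  st$n_donors <- as.integer(n_donors)
  st$seed <- as.integer(seed)
  st$notes <- notes
  st
}

# draw one donor value per target from the n_donors observed cases with
# closest predicted mean; donors pre-sorted by eta so each lookup is a
# binary search plus a 2k-wide window scan
pmm_draw <- function(eta_mis, obs_values, eta_obs, n_donors) {
  k <- min(n_donors, length(obs_values))
  ord <- order(eta_obs)
  eta_s <- eta_obs[ord]
  val_s <- obs_values[ord]
  n <- length(eta_s)
  m <- length(eta_mis)
  pos <- findInterval(eta_mis, eta_s)
  pick <- sample.int(k, m, replace = TRUE)
  # candidate window of 2k donors around the insertion point
  cand_raw <- outer(pos, seq.int(-k + 1L, k), "+")
  cand <- pmin(pmax(cand_raw, 1L), n)
  dist <- abs(matrix(eta_s[cand], m) - eta_mis)
  dist[cand_raw != cand] <- Inf  # clamped duplicates never selected
  out <- numeric(m)
  for (r in seq_len(k)) {
    # r-th nearest donor for every target in one pass
    nearest <- max.col(-dist, ties.method = "first")
    sel <- pick == r
    out[sel] <- val_s[cand[cbind(which(sel), nearest[sel])]]
    dist[cbind(seq_len(m), nearest)] <- Inf
  }
  out
}

#' Apply a fitted strategy to (new) data
#'
#' Completes the lab columns of \code{data} using only the frozen training
#' state. Observed entries are never altered. Numeric strategies return fully
#' complete lab columns; the categorical strategy returns four-level factors
#' in which missingness survives as the "unknown" level.
#'
#' @param state An \code{imputer_state} from \code{\link{fit_imputer}}.
#' @param data A \code{cohort_table} with the same lab columns.
#' @return \code{data} with lab columns completed (or encoded).
#' @export
apply_imputer <- function(state, data) {
  stopifnot(inherits(state, "imputer_state"))
  lnames <- state$lab_names
  missing_cols <- setdiff(lnames, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing lab column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (state$locf) data <- locf_augment(data, state$labs)
  switch(state$strategy,
    mean = {
      for (l in lnames) {
        data[[l]][is.na(data[[l]])] <- state$means[[l]]
      }
      data
    },
    normal_value = {
      for (l in lnames) {
        data[[l]][is.na(data[[l]])] <- state$normal_values[[l]]
      }
      data
    },
    categorical = categorical_encode(state$labs, data),
    pmm = apply_pmm(state, data))
}

apply_pmm <- function(state, data) {
  lnames <- state$lab_names
  X <- as.matrix(data[, lnames, drop = FALSE])
  M <- is.na(X)
  if (!any(M)) return(data)
  demo <- demographic_design(data)
  with_seed(state$seed + 1L, {
    # initialise from training donor pools, then sweep with frozen models
    for (j in seq_along(lnames)) {
      if (any(M[, j])) {
        X[M[, j], j] <- sample(state$models[[j]]$donor_values,
                               sum(M[, j]), replace = TRUE)
      }
    }
    for (iter in seq_len(state$n_iterations)) {
      for (j in seq_along(lnames)) {
        mis <- M[, j]
        if (!any(mis)) next
        mod <- state$models[[j]]
        if (is.null(mod$coefficients)) {
          eta_mis <- rep(mean(mod$donor_values), sum(mis))
        } else {
          design <- cbind(1, X[mis, -j, drop = FALSE], demo[mis, , drop = FALSE])
          eta_mis <- drop(design %*% mod$coefficients)
        }
        X[mis, j] <- pmm_draw(eta_mis, mod$donor_values, mod$donor_eta,
                              state$n_donors)
      }
    }
  })
  for (j in seq_along(lnames)) data[[lnames[j]]] <- X[, j]
  data
}

#' Normal-value imputation
#'
#' Replaces each missing entry of lab \eqn{j} with the midpoint of its
#' clinical normal range, \eqn{(\mathrm{lower\_normal}_j +
#' \mathrm{upper\_normal}_j)/2} — e.g. 13.5 for BUN, 4.25 for potassium.
#' Stateless (the normal ranges are expert knowledge, not estimated).
#'
#' @param config A \code{\link{lab_config}}.
#' @param data A cohort table.
#' @return \code{data} with complete lab columns.
#' @export
normal_value_impute <- function(config, data) {
  lnames <- check_lab_schema(data, config, data_side = TRUE)
  for (l in lnames) {
    nv <- config$normal_value[match(l, config$name)]
    data[[l]][is.na(data[[l]])] <- nv
  }
  data
}

#' Categorical encoding of lab values
#'
#' Encodes each lab as a four-level factor using the normal-range cut points:
#' missing is "unknown", below the lower normal bound is "low", above the
#' upper bound is "high", otherwise "normal". Completes the data without any
#' mechanism assumption and lets classifiers use missingness itself as a
#' feature.
#'
#' @inheritParams normal_value_impute
#' @return \code{data} with lab columns as factors with levels
#'   \code{c("unknown", "low", "normal", "high")}.
#' @export
categorical_encode <- function(config, data) {
  lnames <- check_lab_schema(data, config, data_side = TRUE)
  for (l in lnames) {
    i <- match(l, config$name)
    x <- data[[l]]
    lev <- ifelse(is.na(x), "unknown",
           ifelse(x < config$lower_normal[i], "low",
           ifelse(x > config$upper_normal[i], "high", "normal")))
    data[[l]] <- factor(lev, levels = c("unknown", "low", "normal", "high"))
  }
  data
}

#' Last observation carried forward
#'
#' Within each patient (rows ordered by \code{block_index}), each missing lab
#' entry takes the most recent earlier observed value of the same lab.
#' Leading missing entries stay missing, and values never cross patient
#' boundaries.
#'
#' @param data A cohort table with \code{patient_id} and \code{block_index}.
#' @param labs A \code{\link{lab_config}}.
#' @return \code{data} with forward-filled lab columns.
#' @export
locf_augment <- function(data, labs = lab_config()) {
  lnames <- cohort_lab_names(data, labs)
  pid <- data$patient_id
  same_patient <- pid[-1] == pid[-length(pid)]
  if (nrow(data) > 1 &&
      any(same_patient & diff(data$block_index) <= 0)) {
    stop("blocks must be ordered by block_index within patient")
  }
  for (l in lnames) {
    x <- data[[l]]
    obs <- !is.na(x)
    # index of most recent observation at or before each row
    last_obs <- cummax(ifelse(obs, seq_along(x), 0L))
    # reset at patient boundaries: first row index of each patient's run
    run_start <- c(1L, which(pid[-1] != pid[-length(pid)]) + 1L)
    patient_start <- rep(run_start, diff(c(run_start, length(pid) + 1L)))
    fill <- last_obs >= patient_start & last_obs > 0L
    x[fill] <- x[last_obs[fill]]
    data[[l]] <- x
  }
  data
}

#' Plausibility QC report
#'
#' Counts observed values outside each lab's plausibility limits. Such values
#' are retained (no winsorisation), but flagged for review.
#'
#' @inheritParams locf_augment
#' @return Data frame with per-lab counts below/above the limits.
#' @export
qc_plausibility <- function(data, labs = lab_config()) {
  lnames <- cohort_lab_names(data, labs)
  do.call(rbind, lapply(lnames, function(l) {
    i <- match(l, labs$name)
    x <- data[[l]]
    data.frame(lab = l,
               n_below_limit = sum(x < labs$lower_limit[i], na.rm = TRUE),
               n_above_limit = sum(x > labs$upper_limit[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Serialise / restore an imputer state
#'
#' JSON round-trip of the fitted strategy state, for audit and deployment.
#'
#' @param state An \code{imputer_state}.
#' @param path File path.
#' @export
imputer_to_json <- function(state, path) {
  out <- unclass(state)
  out$labs <- as.data.frame(unclass(out$labs))
  for (f in c("means", "n_obs", "normal_values")) {
    if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])  # keep names in JSON
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname imputer_to_json
#' @export
imputer_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  labs <- as.data.frame(raw$labs)
  class(labs) <- c("lab_config", "data.frame")
  raw$labs <- labs
  for (f in c("means", "n_obs", "normal_values")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$models)) {
    raw$models <- lapply(raw$models, function(m) {
      list(coefficients = if (length(m$coefficients)) unlist(m$coefficients) else NULL,
           donor_values = unlist(m$donor_values),
           donor_eta = unlist(m$donor_eta))
    })
  }
  structure(raw, class = "imputer_state")
}

# numeric design matrix of the demographic predictors
demographic_design <- function(data) {
  cols <- intersect(c("age", "sex", "race", "admission_type"), names(data))
  if (length(cols) == 0) return(matrix(0, nrow(data), 0))
  f <- stats::as.formula(paste("~", paste(cols, collapse = "+")))
  stats::model.matrix(f, data = data)[, -1, drop = FALSE]
}

check_lab_schema <- function(data, labs, data_side = FALSE) {
  lnames <- cohort_lab_names(data, labs)
  if (length(lnames) == 0) stop("no lab columns found in data")
  if (data_side) {
    known <- lnames %in% labs$name
    if (!all(known)) stop("lab absent from config: ",
                          paste(lnames[!known], collapse = ", "))
  }
  lnames
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
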