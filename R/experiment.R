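#' Patient-level train/test split
#'
#' Partitions patient ids at random so that every block of a patient lands on
#' exactly one side — the leakage guard for longitudinal data.
#'
#' @param cohort A \code{cohort_table}.
#' @param fraction Training fraction in (0, 1), default 0.80.
#' @param seed Seed.
#' @return List with \code{train} and \code{test} cohort tables.
#' @export
split_patients <- function(cohort, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  patients <- unique(cohort$patient_id)
  if (length(patients) < 2) stop("need >= 2 patients to split")
  n_train <- round(fraction * length(patients))
  n_train <- min(max(n_train, 1L), length(patients) - 1L)
  train_ids <- with_seed(seed, sample(patients, n_train))
  train <- cohort[cohort$patient_id %in% train_ids, ]
  test <- cohort[!cohort$patient_id %in% train_ids, ]
  class(train) <- class(test) <- class(cohort)
  list(train = train, test = test)
}

STRATEGIES <- c("mean", "pmm", "normal_value", "categorical")

#' Experiment grid
#'
#' The full comparison design: for each classifier a no-lab baseline, the
#' four fill-in strategies with and without LOCF, and the missingness
#' embedding for the neural models (the embedding consumes raw incomplete
#' data, so it never pairs with LOCF, and it requires a network to train its
#' weights, so it never pairs with the lasso). Invalid combinations are
#' rejected at construction.
#'
#' @param cells Optional data frame with columns \code{strategy}
#'   ("none", "mean", "pmm", "normal_value", "categorical", "embedding"),
#'   \code{locf} (logical) and \code{classifier} ("lasso", "mlp", "lstm").
#'   Default: the full design (3 baselines + 4 strategies x 2 LOCF x 3
#'   classifiers + embedding x {mlp, lstm} = 29 cells).
#' @param lab_subset "all", "regular", "informative" — the lab panel used by
#'   every non-baseline cell.
#' @param split_fraction,split_seed Patient-level train fraction and seed.
#' @param n_boot Bootstrap resamples per cell (>= 200).
#' @param eval_seed Seed for the bootstrap.
#' @param mlp_config,lstm_config \code{\link{classifier_config}}s for the
#'   neural cells.
#' @param pmm_iterations Chained-equation sweeps for pmm cells.
#' @return An \code{experiment_grid}.
#' @export
experiment_grid <- function(cells = NULL,
                            lab_subset = "all",
                            split_fraction = 0.8, split_seed = 1L,
                            n_boot = 200L, eval_seed = 1L,
                            mlp_config = classifier_config(),
                            lstm_config = classifier_config(hidden = 16L, lr = 3e-3,
                                                            epochs = 30L),
                            pmm_iterations = 10L) {
  if (is.null(cells)) {
    base <- data.frame(strategy = "none", locf = FALSE,
                       classifier = c("lasso", "mlp", "lstm"))
    strat <- expand.grid(strategy = STRATEGIES, locf = c(FALSE, TRUE),
                         classifier = c("lasso", "mlp", "lstm"),
                         stringsAsFactors = FALSE)
    emb <- data.frame(strategy = "embedding", locf = FALSE,
                      classifier = c("mlp", "lstm"))
    cells <- rbind(base, strat, emb)
  }
  validate_cells(cells)
  structure(list(cells = cells, lab_subset = lab_subset,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 n_boot = as.integer(n_boot),
                 eval_seed = as.integer(eval_seed),
                 mlp_config = mlp_config, lstm_config = lstm_config,
                 pmm_iterations = as.integer(pmm_iterations)),
            class = "experiment_grid")
}

validate_cells <- function(cells) {
  stopifnot(all(c("strategy", "locf", "classifier") %in% names(cells)))
  ok_strategy <- cells$strategy %in% c("none", STRATEGIES, "embedding")
  if (!all(ok_strategy)) stop("unknown strategy in grid")
  if (!all(cells$classifier %in% c("lasso", "mlp", "lstm"))) {
    stop("unknown classifier in grid")
  }
  bad_emb <- cells$strategy == "embedding" & cells$classifier == "lasso"
  if (any(bad_emb)) {
    stop("the embedding strategy pairs only with the neural models (mlp, lstm)")
  }
  bad_locf <- cells$locf & cells$strategy %in% c("embedding", "none")
  if (any(bad_locf)) stop("locf never pairs with embedding or the baseline")
  invisible(cells)
}

#' Run the comparison grid
#'
#' Splits the cohort at the patient level, then for every grid cell fits the
#' strategy on the training side only, applies it to both sides, trains the
#' classifier, scores the test side and evaluates the stratified weighted
#' AUROC with a patient-level bootstrap CI. Cell failures are isolated: the
#' failing cell's row carries the error message, the rest of the grid runs.
#' Fully deterministic given the grid seeds (each cell's classifier seed is
#' derived from \code{seed} and the cell index).
#'
#' @param grid An \code{\link{experiment_grid}}.
#' @param cohort A \code{cohort_table}.
#' @param labs A \code{\link{lab_config}}.
#' @param seed Master seed fanned out to per-cell seeds.
#' @return Data frame with one row per cell: strategy, locf, classifier,
#'   auroc, ci_low, ci_high, n_test_blocks, error.
#' @export
run_grid <- function(grid, cohort, labs = lab_config(), seed = 1L) {
  stopifnot(inherits(grid, "experiment_grid"))
  parts <- split_patients(cohort, grid$split_fraction, grid$split_seed)
  res <- vector("list", nrow(grid$cells))
  for (i in seq_len(nrow(grid$cells))) {
    cell <- grid$cells[i, ]
    res[[i]] <- tryCatch(
      run_cell(cell, parts, grid, labs, seed = seed + 101L * i),
      error = function(e) {
        data.frame(strategy = cell$strategy, locf = cell$locf,
                   classifier = cell$classifier, auroc = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   n_test_blocks = NA_integer_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

run_cell <- function(cell, parts, grid, labs, seed) {
  train <- parts$train
  test <- parts$test
  lab_subset <- if (cell$strategy == "none") "none" else grid$lab_subset
  lab_mode <- switch(cell$strategy,
    none = "none", mean = "numeric", pmm = "numeric",
    normal_value = "numeric", categorical = "categorical",
    embedding = "embedding")

  if (cell$strategy %in% STRATEGIES) {
    subset_names <- switch(grid$lab_subset,
      all = labs$name,
      regular = labs$name[labs$regular],
      informative = labs$name[!labs$regular])
    sub_labs <- labs[labs$name %in% subset_names, ]
    class(sub_labs) <- class(labs)
    st <- fit_imputer(train, cell$strategy, labs = sub_labs,
                      locf = cell$locf,
                      n_iterations = grid$pmm_iterations, seed = seed)
    train <- apply_imputer(st, train)
    test <- apply_imputer(st, test)
  }

  model <- switch(cell$classifier,
    lasso = fit_lasso_logistic(train, labs, lab_subset = lab_subset,
                               lab_mode = lab_mode, seed = seed),
    mlp = {
      cfg <- grid$mlp_config; cfg$seed <- seed
      fit_mlp(train, labs, lab_subset = lab_subset, lab_mode = lab_mode,
              config = cfg)
    },
    lstm = {
      cfg <- grid$lstm_config; cfg$seed <- seed
      fit_lstm(train, labs, lab_subset = lab_subset, lab_mode = lab_mode,
               config = cfg)
    })
  preds <- prediction_set(model, test)
  if (grid$n_boot > 0) {
    rep_ <- evaluate_predictions(preds, n_boot = grid$n_boot,
                                 seed = grid$eval_seed)
  } else {  # point estimates only (seed-averaged directional studies)
    rep_ <- stratified_weighted_auroc(preds)
    rep_$ci <- c(NA_real_, NA_real_)
  }
  data.frame(strategy = cell$strategy, locf = cell$locf,
             classifier = cell$classifier, auroc = rep_$auroc,
             ci_low = rep_$ci[1], ci_high = rep_$ci[2],
             n_test_blocks = nrow(preds), error = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write grid results as tidy CSV and JSON
#'
#' @param results Data frame from \code{\link{run_grid}}.
#' @param path Output path without extension; writes \code{<path>.csv} and
#'   \code{<path>.json}.
#' @param config Optional list recorded in the JSON for provenance.
#' @export
write_results <- function(results, path, config = NULL) {
  utils::write.csv(results, paste0(path, ".csv"), row.names = FALSE, na = "")
  jsonlite::write_json(list(results = results, config = config),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
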