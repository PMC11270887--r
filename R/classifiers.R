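#' Downstream classifiers
#'
#' Three classifiers for next-block deterioration: L1-penalised logistic
#' regression and a multilayer perceptron, both cross-sectional (every
#' patient-block is treated as an independent observation), and an LSTM over
#' each patient's block sequence (many-to-many: a risk at every block, using
#' only that block and its past). All fits are deterministic given their
#' seeds. Each returns a model whose \code{predict} method emits risks in
#' \code{[0, 1]}, and \code{\link{prediction_set}} pairs those risks with the
#' observation identifiers used by the evaluation stack.
#'
#' @name classifiers
NULL

#' L1-penalised logistic regression
#'
#' Fits \code{glmnet} over its regularisation path and picks the penalty by
#' 10-fold cross-validated deviance with folds assigned at the patient level
#' (all blocks of a patient share a fold, so no patient straddles folds).
#'
#' @param train Training cohort, lab columns already strategy-processed.
#' @param labs A \code{\link{lab_config}}.
#' @param lab_subset "all", "regular", "informative" or "none".
#' @param lab_mode "numeric" or "categorical" (match the applied strategy);
#'   "none" for the no-lab baseline.
#' @param nfolds Cross-validation folds (default 10).
#' @param lambda Optional penalty grid.
#' @param seed Seed for fold assignment.
#' @return Object of class \code{lasso_model}.
#' @export
fit_lasso_logistic <- function(train, labs = lab_config(),
                               lab_subset = "all", lab_mode = "numeric",
                               nfolds = 10L, lambda = NULL, seed = 1L) {
  if (lab_subset == "none") lab_mode <- "none"
  spec <- feature_spec(train, labs, lab_subset = lab_subset,
                       lab_mode = lab_mode)
  X <- build_design(spec, train)
  if (any(!is.finite(X))) stop("non-finite features")
  y <- train$outcome
  patients <- unique(train$patient_id)
  fold_of <- with_seed(seed,
                       sample(rep_len(seq_len(nfolds), length(patients))))
  foldid <- fold_of[match(train$patient_id, patients)]
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                             lambda = lambda, type.measure = "deviance")
  structure(list(cvfit = cvfit, spec = spec), class = "lasso_model")
}

#' @rdname fit_lasso_logistic
#' @param object A fitted \code{lasso_model}.
#' @param newdata Cohort table to score.
#' @param ... Unused.
#' @export
predict.lasso_model <- function(object, newdata, ...) {
  X <- build_design(object$spec, newdata)
  drop(stats::predict(object$cvfit, newx = X, s = "lambda.min",
                      type = "response"))
}

#' Neural classifier configuration
#'
#' Hyperparameters for \code{\link{fit_mlp}} / \code{\link{fit_lstm}} and the
#' search space plus budget knobs consumed by \code{\link{tune}}.
#'
#' @param hidden Integer vector of hidden-layer widths (MLP) or the hidden
#'   state size (LSTM). At least one hidden layer.
#' @param dropout Dropout rate (MLP only).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (rows for the MLP, patients for the LSTM).
#' @param pos_weight Positive-class weight in the cross-entropy loss
#'   (1 = unweighted).
#' @param patience Early-stopping patience, in epochs, on validation loss.
#' @param max_epochs_per_trial,elimination_factor Successive-halving budget
#'   knobs: the largest per-trial epoch budget R and the factor eta by which
#'   trials are culled and budgets grown between rounds.
#' @param seed Seed governing initialisation, shuffling and dropout.
#' @return A \code{classifier_config} list.
#' @export
classifier_config <- function(hidden = c(32L, 16L), dropout = 0.1,
                              lr = 1e-3, epochs = 25L, batch_size = 256L,
                              pos_weight = 1, patience = 5L,
                              max_epochs_per_trial = 9L,
                              elimination_factor = 3,
                              seed = 1L) {
  if (length(hidden) < 1 || any(hidden < 1)) {
    stop("at least one hidden layer with >= 1 units is required")
  }
  if (elimination_factor <= 1) stop("elimination_factor must exceed 1")
  if (max_epochs_per_trial < 1) stop("max_epochs_per_trial must be >= 1")
  structure(list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 pos_weight = pos_weight, patience = as.integer(patience),
                 max_epochs_per_trial = as.integer(max_epochs_per_trial),
                 elimination_factor = elimination_factor,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# patient-level validation split used for early stopping
holdout_patients <- function(ids, fraction, seed) {
  patients <- unique(ids)
  with_seed(seed, {
    nval <- max(1L, round(fraction * length(patients)))
    val <- sample(patients, nval)
  })
  ids %in% val
}

#' Multilayer perceptron
#'
#' Cross-sectional feed-forward network (ReLU hidden layers, sigmoid output,
#' binary cross-entropy, Adam, dropout, early stopping on a patient-level
#' validation split). With \code{lab_mode = "embedding"} the missingness-
#' embedding encoder is part of the network and its weight matrices are
#' trained jointly with the dense layers, consuming raw incomplete labs
#' directly.
#'
#' @inheritParams fit_lasso_logistic
#' @param lab_mode "numeric", "categorical", "embedding" or "none".
#' @param demo_encode "onehot" or "embedding" for sex/race/admission type.
#' @param config A \code{\link{classifier_config}}.
#' @param val_fraction Patient fraction held out for early stopping.
#' @param emb_d Embedding dimension per lab (default \code{default_dim(2)}).
#' @return Object of class \code{mlp_model}.
#' @export
fit_mlp <- function(train, labs = lab_config(), lab_subset = "all",
                    lab_mode = "numeric", demo_encode = "onehot",
                    config = classifier_config(), val_fraction = 0.15,
                    emb_d = default_dim(2L)) {
  if (lab_subset == "none") lab_mode <- "none"
  spec <- feature_spec(train, labs, lab_subset = lab_subset,
                       lab_mode = lab_mode, demo_encode = demo_encode)
  input <- build_input(spec, train)
  emb <- make_emb_params(spec, emb_d, config$seed)
  demo <- make_demo_tables(spec, config$seed)
  params <- mlp_init(input_width(spec, emb_d), config$hidden,
                     seed = config$seed, emb = emb, demo = demo)
  is_val <- holdout_patients(train$patient_id, val_fraction,
                             config$seed + 7L)
  fit <- mlp_train(params,
                   subset_input(input, which(!is_val)), train$outcome[!is_val],
                   subset_input(input, which(is_val)), train$outcome[is_val],
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$lr, dropout = config$dropout,
                   pos_weight = config$pos_weight,
                   patience = config$patience, seed = config$seed)
  structure(list(params = fit$params, spec = spec, config = config,
                 emb_d = emb_d, val_loss = fit$val_loss,
                 history = fit$history),
            class = "mlp_model")
}

#' @rdname fit_mlp
#' @param object A fitted \code{mlp_model}.
#' @param newdata Cohort table to score.
#' @param ... Unused.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  input <- build_input(object$spec, newdata)
  mlp_forward(object$params, input)$p
}

#' LSTM sequence classifier
#'
#' Recurrent network over each patient's sequence of 12-hour blocks
#' (sequences padded to \code{max_blocks} and masked out of the loss),
#' emitting a deterioration risk at every block from the hidden state at that
#' block — predictions are causal in the block index. Supports the same lab
#' modes as the MLP, including the jointly-trained missingness embedding;
#' demographics enter at every time step.
#'
#' @inheritParams fit_mlp
#' @param max_blocks Maximum sequence length (14).
#' @return Object of class \code{lstm_model}.
#' @export
fit_lstm <- function(train, labs = lab_config(), lab_subset = "all",
                     lab_mode = "numeric", demo_encode = "onehot",
                     config = classifier_config(hidden = 16L, lr = 3e-3,
                                                epochs = 30L),
                     val_fraction = 0.15, emb_d = default_dim(2L),
                     max_blocks = 14L) {
  if (lab_subset == "none") lab_mode <- "none"
  spec <- feature_spec(train, labs, lab_subset = lab_subset,
                       lab_mode = lab_mode, demo_encode = demo_encode)
  seqs <- build_seqs(spec, train, max_blocks)
  emb <- make_emb_params(spec, emb_d, config$seed)
  demo <- make_demo_tables(spec, config$seed)
  params <- lstm_init(input_width(spec, emb_d), config$hidden[1],
                      seed = config$seed, emb = emb, demo = demo)
  is_val_p <- holdout_patients(seqs$patients, val_fraction, config$seed + 7L)
  fit <- lstm_train(params,
                    subset_seqs(seqs, which(!is_val_p)),
                    subset_seqs(seqs, which(is_val_p)),
                    epochs = config$epochs, batch_size = config$batch_size,
                    lr = config$lr, pos_weight = config$pos_weight,
                    patience = config$patience, seed = config$seed)
  structure(list(params = fit$params, spec = spec, config = config,
                 emb_d = emb_d, max_blocks = as.integer(max_blocks),
                 val_loss = fit$val_loss, history = fit$history),
            class = "lstm_model")
}

#' @rdname fit_lstm
#' @param object A fitted \code{lstm_model}.
#' @param newdata Cohort table to score.
#' @param ... Unused.
#' @export
predict.lstm_model <- function(object, newdata, ...) {
  seqs <- build_seqs(object$spec, newdata, object$max_blocks)
  p <- lstm_forward(object$params, seqs)$p
  p[cbind(seqs$row_patient, seqs$row_t)]
}

make_emb_params <- function(spec, emb_d, seed) {
  if (spec$lab_mode != "embedding") return(NULL)
  p <- length(spec$lab_names)
  with_seed(seed + 11L,
            list(obs = matrix(stats::rnorm(p * emb_d, 0, 0.1), p, emb_d,
                              dimnames = list(spec$lab_names, NULL)),
                 mis = matrix(stats::rnorm(p * emb_d, 0, 0.1), p, emb_d,
                              dimnames = list(spec$lab_names, NULL))))
}

make_demo_tables <- function(spec, seed, d = 2L) {
  if (spec$demo_encode != "embedding") return(NULL)
  with_seed(seed + 13L,
            lapply(spec$demo_levels, function(lev) {
              matrix(stats::rnorm((length(lev) + 1L) * d, 0, 0.1),
                     length(lev) + 1L, d,
                     dimnames = list(c(lev, "(other)"), NULL))
            }))
}

#' Prediction set
#'
#' Pairs model risks with the observation identifiers (patient, block) and
#' true outcomes — the unit of account for all evaluation functions.
#'
#' @param model A fitted classifier.
#' @param data Cohort table to score.
#' @return Data frame with \code{patient_id}, \code{block_index},
#'   \code{risk}, \code{outcome}.
#' @export
prediction_set <- function(model, data) {
  data.frame(patient_id = data$patient_id,
             block_index = data$block_index,
             risk = as.numeric(stats::predict(model, data)),
             outcome = data$outcome)
}

#' Successive-halving hyperparameter search
#'
#' Random-search tuner with the two budget knobs that parametrise one
#' bracket of a bandit-style scheduler: candidates are all trained for a
#' small epoch budget, the best \code{1/eta} fraction survives, the budget is
#' multiplied by \code{eta}, and the process repeats until the budget reaches
#' \code{R} (\code{max_epochs_per_trial}). If the budget admits no halving
#' round (\code{R < eta} with more than one candidate), the tuner degrades to
#' plain random search at budget \code{R} and says so in the returned log.
#' Ties are broken by candidate order.
#'
#' @param candidates List of candidate hyperparameter sets.
#' @param train_fn Function \code{(candidate, epochs)} returning a validation
#'   loss; must be deterministic given its arguments.
#' @param R Maximum epochs a trial can run.
#' @param eta Trial elimination factor (> 1).
#' @return List with \code{best} (the winning candidate), \code{best_loss},
#'   and a per-round \code{log} data frame.
#' @export
tune <- function(candidates, train_fn, R = 9L, eta = 3) {
  if (length(candidates) == 0) stop("no candidates")
  if (eta <= 1) stop("eta must exceed 1")
  if (R < 1) stop("R must be >= 1")
  n <- length(candidates)
  idx <- seq_len(n)
  log <- list()
  if (n > 1 && R < eta) {
    losses <- vapply(idx, function(i) train_fn(candidates[[i]], R), 0)
    log[[1]] <- data.frame(round = 1L, candidate = idx, epochs = R,
                           loss = losses, note = "random-search fallback")
    best <- idx[which.min(losses)]
    return(list(best = candidates[[best]], best_index = best,
                best_loss = min(losses), log = do.call(rbind, log)))
  }
  s <- if (n > 1) floor(log(n) / log(eta)) else 0
  budget <- max(1L, as.integer(floor(R / eta^s)))
  round <- 0L
  repeat {
    round <- round + 1L
    losses <- vapply(idx, function(i) train_fn(candidates[[i]], budget), 0)
    log[[round]] <- data.frame(round = round, candidate = idx,
                               epochs = budget, loss = losses, note = "")
    if (length(idx) == 1L || budget >= R) break
    keep <- max(1L, floor(length(idx) / eta))
    idx <- idx[order(losses)[seq_len(keep)]]  # ties: earlier candidate wins
    budget <- min(as.integer(R), as.integer(budget * eta))
  }
  final <- log[[round]]
  best <- final$candidate[which.min(final$loss)]
  list(best = candidates[[best]], best_index = best,
       best_loss = min(final$loss), log = do.call(rbind, log))
}
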