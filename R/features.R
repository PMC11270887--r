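# Feature assembly: turns a (strategy-processed or raw) cohort table into
# model inputs, with every data-dependent constant (factor levels, centers,
# scales) learned on the training set and frozen in a feature_spec, so the
# same transform applies verbatim to test data.

DEMO_COLS <- c("age", "sex", "race", "admission_type")

#' Feature specification
#'
#' Captures how cohort rows map to model inputs: which labs enter and how
#' (dense numeric, categorical dummies, raw + mask for the missingness
#' embedding, or none for the no-lab baseline), demographic encoding, and the
#' standardisation constants estimated from training data. The time block
#' index enters as a standardised numeric predictor.
#'
#' @param train Training cohort (already strategy-processed unless
#'   \code{lab_mode = "embedding"} or \code{"none"}).
#' @param labs A \code{\link{lab_config}}.
#' @param lab_subset One of "all", "regular", "informative", "none".
#' @param lab_mode How labs enter: "numeric" (complete numeric columns),
#'   "categorical" (four-level factors), "embedding" (raw values + mask),
#'   "none".
#' @param demo_encode "onehot" or "embedding" (trainable tables, neural
#'   models only).
#' @return A \code{feature_spec}.
#' @export
feature_spec <- function(train, labs = lab_config(),
                         lab_subset = c("all", "regular", "informative", "none"),
                         lab_mode = c("numeric", "categorical", "embedding", "none"),
                         demo_encode = c("onehot", "embedding")) {
  lab_subset <- match.arg(lab_subset)
  lab_mode <- match.arg(lab_mode)
  demo_encode <- match.arg(demo_encode)
  if (lab_subset == "none") lab_mode <- "none"
  lnames <- switch(lab_subset,
    all = labs$name,
    regular = labs$name[labs$regular],
    informative = labs$name[!labs$regular],
    none = character(0))
  lnames <- intersect(lnames, names(train))

  lab_stats <- NULL
  lab_levels <- NULL
  if (lab_mode == "numeric") {
    lab_stats <- lapply(lnames, function(l) {
      x <- train[[l]]
      if (anyNA(x)) stop("lab ", l, " still has missing values; apply a strategy first")
      s <- stats::sd(x)
      list(center = mean(x), scale = if (is.finite(s) && s > 0) s else 1)
    })
    names(lab_stats) <- lnames
  } else if (lab_mode == "categorical") {
    lab_levels <- c("unknown", "low", "normal", "high")
  } else if (lab_mode == "embedding") {
    lab_stats <- lapply(lnames, function(l) {
      obs <- train[[l]][!is.na(train[[l]])]
      s <- stats::sd(obs)
      list(center = mean(obs), scale = if (is.finite(s) && s > 0) s else 1)
    })
    names(lab_stats) <- lnames
  }

  demo_levels <- lapply(intersect(c("sex", "race", "admission_type"),
                                  names(train)),
                        function(v) {
                          x <- train[[v]]
                          if (is.factor(x)) levels(x) else
                            sort(unique(as.character(x)))
                        })
  names(demo_levels) <- intersect(c("sex", "race", "admission_type"),
                                  names(train))
  structure(list(lab_subset = lab_subset, lab_mode = lab_mode,
                 lab_names = lnames, lab_stats = lab_stats,
                 lab_levels = lab_levels,
                 demo_encode = demo_encode, demo_levels = demo_levels,
                 age_center = mean(train$age),
                 age_scale = max(stats::sd(train$age), 1e-8),
                 block_center = mean(train$block_index),
                 block_scale = max(stats::sd(train$block_index), 1e-8)),
            class = "feature_spec")
}

# dense demographic block (one-hot) + standardised age and block index
demo_matrix <- function(spec, data) {
  out <- cbind(age = (data$age - spec$age_center) / spec$age_scale,
               block = (data$block_index - spec$block_center) / spec$block_scale)
  for (v in names(spec$demo_levels)) {
    lev <- spec$demo_levels[[v]]
    if (length(lev) < 2) next  # constant variable carries no contrast
    x <- as.character(data[[v]])
    # indicators built by comparison: values outside the declared levels get
    # all-zero columns (treated as the reference) instead of dropped rows
    mm <- vapply(lev[-1], function(l) as.numeric(x == l),
                 numeric(length(x)))
    mm <- matrix(mm, nrow = length(x),
                 dimnames = list(NULL, paste0(v, "_", lev[-1])))
    out <- cbind(out, mm)
  }
  out
}

demo_index_matrix <- function(spec, data) {
  vs <- names(spec$demo_levels)
  idx <- vapply(vs, function(v) {
    i <- match(as.character(data[[v]]), spec$demo_levels[[v]])
    i[is.na(i)] <- length(spec$demo_levels[[v]]) + 1L  # reserved "(other)"
    i
  }, integer(nrow(data)))
  matrix(idx, nrow = nrow(data), dimnames = list(NULL, vs))
}

lab_matrix <- function(spec, data) {
  switch(spec$lab_mode,
    none = NULL,
    numeric = {
      cols <- lapply(spec$lab_names, function(l) {
        st <- spec$lab_stats[[l]]
        (data[[l]] - st$center) / st$scale
      })
      out <- do.call(cbind, cols)
      colnames(out) <- spec$lab_names
      if (anyNA(out)) stop("missing lab values; apply a strategy first")
      out
    },
    categorical = {
      cols <- lapply(spec$lab_names, function(l) {
        x <- factor(as.character(data[[l]]), levels = spec$lab_levels)
        if (anyNA(x)) stop("lab ", l, " has values outside the encoding levels")
        mm <- stats::model.matrix(~ x - 1)
        colnames(mm) <- paste0(l, "_", spec$lab_levels)
        mm[, -1, drop = FALSE]  # "unknown" as reference
      })
      do.call(cbind, cols)
    },
    embedding = stop("lab_mode 'embedding' has no dense lab matrix"))
}

# nn input list for cross-sectional models
build_input <- function(spec, data) {
  input <- list()
  if (spec$lab_mode == "embedding") {
    Xz <- vapply(spec$lab_names, function(l) {
      st <- spec$lab_stats[[l]]
      z <- (data[[l]] - st$center) / st$scale
      z[is.na(z)] <- 0
      z
    }, numeric(nrow(data)))
    M <- vapply(spec$lab_names, function(l) as.numeric(is.na(data[[l]])),
                numeric(nrow(data)))
    input$Xz <- matrix(Xz, nrow = nrow(data))
    input$M <- matrix(M, nrow = nrow(data))
  }
  if (spec$demo_encode == "embedding") {
    input$demo_idx <- demo_index_matrix(spec, data)
    dm <- demo_matrix(spec, data)
    input$Z <- dm[, c("age", "block"), drop = FALSE]
  } else {
    input$Z <- demo_matrix(spec, data)
  }
  if (spec$lab_mode %in% c("numeric", "categorical")) {
    input$Z <- cbind(input$Z, lab_matrix(spec, data))
  }
  input
}

# flat design matrix for glmnet
build_design <- function(spec, data) {
  if (spec$lab_mode == "embedding") {
    stop("the embedding encoder pairs only with the neural models")
  }
  inp <- build_input(spec, data)
  inp$Z
}

input_width <- function(spec, emb_d = 2L) {
  n_demo <- 2 + sum(vapply(spec$demo_levels, length, 0L) - 1L)
  if (spec$demo_encode == "embedding") {
    n_demo <- 2 + length(spec$demo_levels) * emb_d
  }
  n_lab <- switch(spec$lab_mode,
    none = 0L,
    numeric = length(spec$lab_names),
    categorical = 3L * length(spec$lab_names),
    embedding = length(spec$lab_names) * emb_d)
  n_demo + n_lab
}

# per-patient padded sequences for the LSTM; keeps a row map back to the
# original block order
build_seqs <- function(spec, data, max_blocks = 14L) {
  pid <- data$patient_id
  patients <- unique(pid)
  n <- length(patients)
  Tn <- max_blocks
  if (any(data$block_index >= Tn)) stop("sequence longer than max_blocks")
  prow <- match(pid, patients)
  mask <- matrix(0, n, Tn)
  y <- matrix(0, n, Tn)
  tcol <- data$block_index + 1L
  mask[cbind(prow, tcol)] <- 1
  y[cbind(prow, tcol)] <- data$outcome

  full <- build_input(spec, data)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    sel <- tcol == t
    step <- list()
    for (f in c("Z", "Xz", "M")) {
      if (!is.null(full[[f]])) {
        mat <- matrix(0, n, ncol(full[[f]]))
        mat[prow[sel], ] <- full[[f]][sel, , drop = FALSE]
        step[[f]] <- mat
      }
    }
    if (!is.null(full$demo_idx)) {
      mat <- matrix(1L, n, ncol(full$demo_idx))
      mat[prow[sel], ] <- full$demo_idx[sel, , drop = FALSE]
      step$demo_idx <- mat
    }
    steps[[t]] <- step
  }
  list(steps = steps, mask = mask, y = y,
       patients = patients, row_patient = prow, row_t = tcol)
}
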