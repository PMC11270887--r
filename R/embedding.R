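#' Default embedding dimension
#'
#' Rule-of-thumb dimension for an embedding of a categorical state variable
#' with \code{k} states: the fourth root of \code{k}, rounded up to the next
#' whole number. For the binary missingness state (k = 2) this gives d = 2.
#'
#' @param k Number of states (>= 1).
#' @return Integer embedding dimension.
#' @examples
#' default_dim(2)   # 2
#' default_dim(17)  # 3
#' @export
default_dim <- function(k) {
  if (!is.numeric(k) || any(k < 1)) stop("k must be >= 1")
  as.integer(ceiling(k^0.25 - 1e-9))
}

#' Missingness-embedding specification for one variable
#'
#' A partially observed variable \eqn{x_j} with missingness state
#' \eqn{m_j \in \{0, 1\}} is represented through a trainable weight matrix
#' \eqn{W_j \in R^{k \times d}}: the embedding is the row of \eqn{W_j}
#' selected by the one-hot state vector, \eqn{e_j = W_j m_j}. Conditional
#' scaling incorporates the observed value: when the value is observed the
#' output is \eqn{x_j e_j} (the "observed" row scaled by the standardised
#' value), and when it is missing the "missing" row is used as-is. Fully
#' observed variables bypass the encoder unchanged.
#'
#' Observed values are standardised with training-set mean/SD before scaling
#' so that the raw measurement scale does not dominate the learned rows.
#'
#' @param name Variable name.
#' @param k Number of missingness states (2: observed / missing).
#' @param d Embedding dimension; defaults to \code{default_dim(k)}.
#' @param center,scale Standardisation constants for observed values.
#' @param init_sd SD of the random-normal weight initialisation.
#' @param seed Seed for the initialisation.
#' @return An object of class \code{embedding_spec} with weight matrix
#'   \code{W} (k rows; row 1 = observed state, row 2 = missing state).
#' @export
embedding_spec <- function(name, k = 2L, d = default_dim(k),
                           center = 0, scale = 1,
                           init_sd = 0.1, seed = 1L) {
  if (k < 2) stop("an embedded variable needs at least 2 states")
  W <- with_seed(seed, matrix(stats::rnorm(k * d, 0, init_sd), k, d))
  rownames(W) <- c("observed", "missing", if (k > 2)
    paste0("state", seq_len(k - 2) + 2L))
  structure(list(name = name, k = as.integer(k), d = as.integer(d),
                 W = W, center = center, scale = scale),
            class = "embedding_spec")
}

#' Embed a single value
#'
#' @param spec An \code{\link{embedding_spec}}.
#' @param value A single numeric value or \code{NA} (missing).
#' @return Numeric vector of length \code{spec$d}.
#' @export
embed_variable <- function(spec, value) {
  stopifnot(inherits(spec, "embedding_spec"))
  if (length(value) != 1) stop("embed_variable takes one value")
  if (is.na(value)) return(spec$W["missing", ])
  if (!is.finite(value)) stop("observed value must be finite")
  z <- (value - spec$center) / spec$scale
  z * spec$W["observed", ]
}

#' Missingness-embedding encoder over a lab panel
#'
#' Builds one \code{\link{embedding_spec}} per partially observed lab
#' (standardisation constants estimated from the observed training values)
#' and records which columns pass through unchanged. The encoder is
#' self-sufficient: it consumes raw incomplete data with no prior imputation,
#' and its weights are trained jointly with a downstream network.
#'
#' @param train Training \code{cohort_table}.
#' @param labs A \code{\link{lab_config}}.
#' @param lab_subset Character vector of lab columns to embed (default: all
#'   labs present).
#' @param d Embedding dimension per lab (default \code{default_dim(2)}).
#' @param init_sd,seed Weight initialisation.
#' @return An object of class \code{missingness_encoder}.
#' @export
missingness_encoder <- function(train, labs = lab_config(),
                                lab_subset = NULL,
                                d = default_dim(2L),
                                init_sd = 0.1, seed = 1L) {
  lnames <- cohort_lab_names(train, labs)
  if (!is.null(lab_subset)) lnames <- intersect(lnames, lab_subset)
  if (length(lnames) == 0) stop("no labs to embed")
  specs <- lapply(seq_along(lnames), function(j) {
    x <- train[[lnames[j]]]
    obs <- x[!is.na(x)]
    if (length(obs) < 2) stop("lab ", lnames[j], " has < 2 observed values")
    s <- stats::sd(obs)
    embedding_spec(lnames[j], k = 2L, d = d,
                   center = mean(obs), scale = if (s > 0) s else 1,
                   init_sd = init_sd, seed = seed + j)
  })
  names(specs) <- lnames
  structure(list(specs = specs, lab_names = lnames, d = as.integer(d)),
            class = "missingness_encoder")
}

#' Encode records through the missingness embedding
#'
#' Maps each row of \code{data} to the complete concatenation of per-lab
#' embeddings (length \code{d} per embedded lab) followed by any requested
#' pass-through columns, unchanged. Deterministic given the encoder weights.
#'
#' @param encoder A \code{\link{missingness_encoder}}.
#' @param data A cohort table (or any data frame with the embedded columns).
#' @param passthrough Optional numeric matrix (or data frame column names) of
#'   fully observed features appended unchanged.
#' @return Numeric matrix with \code{nrow(data)} rows.
#' @export
embed_record <- function(encoder, data, passthrough = NULL) {
  stopifnot(inherits(encoder, "missingness_encoder"))
  missing_cols <- setdiff(encoder$lab_names, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks embedded column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(data)
  blocks <- lapply(encoder$specs, function(spec) {
    x <- data[[spec$name]]
    m <- is.na(x)
    z <- (x - spec$center) / spec$scale
    z[m] <- 0
    out <- z %o% spec$W["observed", ]
    out[m, ] <- matrix(spec$W["missing", ], sum(m), spec$d, byrow = TRUE)
    colnames(out) <- paste0(spec$name, "_e", seq_len(spec$d))
    out
  })
  E <- do.call(cbind, blocks)
  if (!is.null(passthrough)) {
    if (is.character(passthrough)) {
      passthrough <- as.matrix(data[, passthrough, drop = FALSE])
    }
    E <- cbind(E, passthrough)
  }
  E
}

#' Categorical-variable embedding
#'
#' A trainable embedding table for a categorical variable (e.g. race or
#' admission type), an alternative to one-hot encoding. All categorical
#' variables share one common dimension for simplicity. Levels unseen at
#' construction map to a reserved "(other)" row (with a warning).
#'
#' @param levels Character vector of declared levels.
#' @param d Embedding dimension (shared across categorical variables).
#' @param init_sd,seed Weight initialisation.
#' @return An object of class \code{categorical_embedding} with a weight
#'   matrix of \code{length(levels) + 1} rows (last = "(other)").
#' @export
categorical_embedding <- function(levels, d = 2L, init_sd = 0.1, seed = 1L) {
  levels <- as.character(levels)
  W <- with_seed(seed,
                 matrix(stats::rnorm((length(levels) + 1) * d, 0, init_sd),
                        length(levels) + 1, d))
  rownames(W) <- c(levels, "(other)")
  structure(list(levels = levels, d = as.integer(d), W = W),
            class = "categorical_embedding")
}

#' @rdname categorical_embedding
#' @param emb A \code{categorical_embedding}.
#' @param value Vector of category values.
#' @return \code{embed_categorical}: matrix of embeddings, one row per value.
#' @export
embed_categorical <- function(emb, value) {
  stopifnot(inherits(emb, "categorical_embedding"))
  idx <- match(as.character(value), emb$levels)
  if (anyNA(idx)) {
    warning("unseen level(s) mapped to the reserved '(other)' row: ",
            paste(unique(value[is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- length(emb$levels) + 1L
  }
  emb$W[idx, , drop = FALSE]
}

#' Serialise / restore a missingness encoder
#'
#' JSON round-trip preserving weights exactly (so encoded outputs reproduce
#' bit-identically).
#'
#' @param encoder A \code{\link{missingness_encoder}}.
#' @param path File path.
#' @export
encoder_to_json <- function(encoder, path) {
  out <- list(d = encoder$d, lab_names = encoder$lab_names,
              specs = lapply(encoder$specs, function(s) {
                list(name = s$name, k = s$k, d = s$d,
                     W = apply(s$W, 1, identity, simplify = FALSE),
                     center = s$center, scale = s$scale)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname encoder_to_json
#' @export
encoder_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw$specs, function(s) {
    W <- do.call(rbind, lapply(s$W, unlist))
    rownames(W) <- c("observed", "missing",
                     if (s$k > 2) paste0("state", seq_len(s$k - 2) + 2L))
    structure(list(name = s$name, k = as.integer(s$k), d = as.integer(s$d),
                   W = W, center = s$center, scale = s$scale),
              class = "embedding_spec")
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(specs = specs,
                 lab_names = unlist(raw$lab_names),
                 d = as.integer(raw$d)),
            class = "missingness_encoder")
}
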