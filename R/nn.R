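# Minimal neural engine: dense layers, the missingness-embedding encoder and
# categorical embedding tables, binary cross-entropy, Adam, dropout, early
# stopping. Written with plain matrix algebra and hand-derived gradients;
# everything is seeded and CPU-sized. Shared by the MLP and LSTM classifiers.

sigmoid <- function(x) stats::plogis(x)

bce_loss <- function(p, y, weight = NULL) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(weight)) mean(ll) else sum(weight * ll) / sum(weight)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# ---- encoder forward/backward ----------------------------------------------
# nn input is a list with any of:
#   Z        n x q dense features (pass-through, already encoded/standardised)
#   Xz, M    n x p standardised lab values (NA -> 0) and missingness mask
#   demo_idx n x v integer level indices for embedded categorical variables
# encoder params: emb$obs, emb$mis (p x d); demo: list of (k_v+1) x d tables

encode_forward <- function(params, input) {
  parts <- list()
  if (!is.null(params$emb)) {
    p <- nrow(params$emb$obs); d <- ncol(params$emb$obs)
    n <- nrow(input$Xz)
    xs <- input$Xz * (1 - input$M)
    E <- matrix(0, n, p * d)
    for (j in seq_len(p)) {
      cols <- (j - 1L) * d + seq_len(d)
      E[, cols] <- xs[, j] %o% params$emb$obs[j, ] +
        input$M[, j] %o% params$emb$mis[j, ]
    }
    parts$E <- E
  }
  if (!is.null(params$demo)) {
    parts$D <- do.call(cbind, lapply(seq_along(params$demo), function(v) {
      params$demo[[v]][input$demo_idx[, v], , drop = FALSE]
    }))
  }
  if (!is.null(input$Z)) parts$Z <- input$Z
  do.call(cbind, parts)
}

encode_backward <- function(params, input, dH0) {
  grads <- list()
  off <- 0L
  if (!is.null(params$emb)) {
    p <- nrow(params$emb$obs); d <- ncol(params$emb$obs)
    xs <- input$Xz * (1 - input$M)
    gobs <- params$emb$obs * 0
    gmis <- params$emb$mis * 0
    for (j in seq_len(p)) {
      cols <- off + (j - 1L) * d + seq_len(d)
      gE <- dH0[, cols, drop = FALSE]
      gobs[j, ] <- colSums(gE * xs[, j])
      gmis[j, ] <- colSums(gE * input$M[, j])
    }
    grads$emb <- list(obs = gobs, mis = gmis)
    off <- off + p * d
  }
  if (!is.null(params$demo)) {
    grads$demo <- vector("list", length(params$demo))
    for (v in seq_along(params$demo)) {
      tab <- params$demo[[v]]
      dcols <- off + seq_len(ncol(tab))
      off <- off + ncol(tab)
      g <- tab * 0
      gD <- dH0[, dcols, drop = FALSE]
      idx <- input$demo_idx[, v]
      for (r in unique(idx)) g[r, ] <- colSums(gD[idx == r, , drop = FALSE])
      grads$demo[[v]] <- g
    }
  }
  grads
}

# ---- MLP --------------------------------------------------------------------

mlp_init <- function(input_dim, hidden, seed = 1L,
                     emb = NULL, demo = NULL) {
  dims <- c(input_dim, hidden, 1L)
  params <- with_seed(seed, {
    layers <- lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                   0, sqrt(2 / dims[i])),
                      dims[i], dims[i + 1L]),
           b = rep(0, dims[i + 1L]))
    })
    p <- list(layers = layers)
    if (!is.null(emb)) p$emb <- emb
    if (!is.null(demo)) p$demo <- demo
    p
  })
}

mlp_forward <- function(params, input, dropout = 0, training = FALSE) {
  H <- encode_forward(params, input)
  L <- length(params$layers)
  cache <- list(H0 = H, A = vector("list", L), Hs = vector("list", L),
                masks = vector("list", L))
  for (i in seq_len(L)) {
    A <- sweep(H %*% params$layers[[i]]$W, 2, params$layers[[i]]$b, "+")
    if (i < L) {
      H <- pmax(A, 0)
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H)) /
          (1 - dropout)
        H <- H * mask
        cache$masks[[i]] <- mask
      }
    } else H <- A
    cache$A[[i]] <- A
    cache$Hs[[i]] <- H
  }
  list(logit = drop(H), p = sigmoid(drop(H)), cache = cache)
}

mlp_backward <- function(params, input, fwd, y, weight = NULL) {
  n <- length(y)
  p <- fwd$p
  w <- if (is.null(weight)) rep(1, n) else weight
  dlogit <- matrix(w * (p - y) / sum(w), ncol = 1)
  L <- length(params$layers)
  glayers <- vector("list", L)
  dH <- dlogit
  for (i in rev(seq_len(L))) {
    Hin <- if (i == 1) fwd$cache$H0 else fwd$cache$Hs[[i - 1L]]
    glayers[[i]] <- list(W = crossprod(Hin, dH), b = colSums(dH))
    dH <- dH %*% t(params$layers[[i]]$W)
    if (i > 1) {
      dH <- dH * (fwd$cache$A[[i - 1L]] > 0)
      if (!is.null(fwd$cache$masks[[i - 1L]])) {
        dH <- dH * fwd$cache$masks[[i - 1L]]
      }
    }
  }
  grads <- list(layers = glayers)
  enc <- encode_backward(params, input, dH)
  grads$emb <- enc$emb
  grads$demo <- enc$demo
  grads[!vapply(grads, is.null, TRUE)]
}

subset_input <- function(input, idx) {
  out <- input
  for (f in c("Z", "Xz", "M", "demo_idx")) {
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][idx, , drop = FALSE]
  }
  out
}

input_nrow <- function(input) {
  for (f in c("Z", "Xz", "demo_idx")) {
    if (!is.null(input[[f]])) return(nrow(input[[f]]))
  }
  stop("empty nn input")
}

mlp_train <- function(params, input, y, val_input = NULL, val_y = NULL,
                      epochs = 30L, batch_size = 256L, lr = 1e-3,
                      dropout = 0, pos_weight = 1, patience = 5L,
                      seed = 1L) {
  n <- input_nrow(input)
  w <- NULL
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        bin <- subset_input(input, idx)
        by <- y[idx]
        bw <- if (pos_weight != 1) ifelse(by == 1, pos_weight, 1) else NULL
        fwd <- mlp_forward(params, bin, dropout = dropout, training = TRUE)
        if (!is.finite(bce_loss(fwd$p, by, bw))) stop("NaN loss; trial aborted")
        grads <- mlp_backward(params, bin, fwd, by, bw)
        upd <- adam_step(params, grads, opt, lr = lr)
        params <- upd$params
        opt <- c(upd$state)
      }
      vloss <- if (!is.null(val_input)) {
        vp <- mlp_forward(params, val_input)$p
        vw <- if (pos_weight != 1) ifelse(val_y == 1, pos_weight, 1) else NULL
        bce_loss(vp, val_y, vw)
      } else {
        tp <- mlp_forward(params, input)$p
        tw <- if (pos_weight != 1) ifelse(y == 1, pos_weight, 1) else NULL
        bce_loss(tp, y, tw)
      }
      history <- c(history, vloss)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  list(params = best$params, val_loss = best$loss, history = history)
}
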