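# LSTM sequence engine (many-to-many): per-patient sequences of 12-hour
# blocks, a risk emitted at every block from the hidden state at that block
# (causal by construction), padding masked out of the loss. Shares the
# encoder (missingness embedding / categorical tables) and Adam with the MLP
# engine; gradients are hand-derived BPTT.
#
# Sequence input: list(steps, mask, y) where steps is a length-T list of nn
# inputs (one per block, rows = patients; padded steps hold zeros), mask is
# the n x T validity matrix and y the n x T outcome matrix.

lstm_init <- function(input_dim, hidden, seed = 1L, emb = NULL, demo = NULL) {
  with_seed(seed, {
    f <- input_dim; h <- hidden
    sc <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(1 / a)), a, b)
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1  # forget-gate bias
    p <- list(cell = list(Wx = sc(f, 4 * h), Wh = sc(h, 4 * h), b = b,
                          Wy = sc(h, 1), by = 0))
    if (!is.null(emb)) p$emb <- emb
    if (!is.null(demo)) p$demo <- demo
    p
  })
}

lstm_forward <- function(params, seqs, keep_cache = FALSE) {
  Tn <- length(seqs$steps)
  n <- nrow(seqs$mask)
  h <- nrow(params$cell$Wh)
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  logits <- matrix(0, n, Tn)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    U <- encode_forward(params, seqs$steps[[t]])
    z <- sweep(U %*% params$cell$Wx + H %*% params$cell$Wh, 2,
               params$cell$b, "+")
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    tc <- tanh(C)
    Hprev <- H
    H <- o * tc
    logits[, t] <- drop(H %*% params$cell$Wy) + params$cell$by
    if (keep_cache) {
      cache[[t]] <- list(U = U, i = i, f = f, g = g, o = o,
                         C = C, Cprev = Cprev, tc = tc, H = H, Hprev = Hprev)
    }
  }
  list(logits = logits, p = sigmoid(logits), cache = cache)
}

lstm_loss <- function(p, seqs, pos_weight = 1) {
  w <- seqs$mask
  if (pos_weight != 1) w <- w * ifelse(seqs$y == 1, pos_weight, 1)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ll <- -(seqs$y * log(pc) + (1 - seqs$y) * log(1 - pc))
  sum(w * ll) / sum(w)
}

lstm_backward <- function(params, seqs, fwd, pos_weight = 1) {
  Tn <- length(seqs$steps)
  h <- nrow(params$cell$Wh)
  w <- seqs$mask
  if (pos_weight != 1) w <- w * ifelse(seqs$y == 1, pos_weight, 1)
  dlogits <- w * (fwd$p - seqs$y) / sum(w)
  g <- list(cell = rapply(params$cell, function(x) x * 0, how = "replace"))
  enc_grads <- NULL
  dH <- matrix(0, nrow(seqs$mask), h)
  dC <- matrix(0, nrow(seqs$mask), h)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dl <- dlogits[, t]
    g$cell$Wy <- g$cell$Wy + crossprod(cc$H, dl)
    g$cell$by <- g$cell$by + sum(dl)
    dH <- dH + dl %o% drop(params$cell$Wy)
    do <- dH * cc$tc
    dCt <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dCt * cc$g
    df <- dCt * cc$Cprev
    dg <- dCt * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    g$cell$Wx <- g$cell$Wx + crossprod(cc$U, dz)
    g$cell$Wh <- g$cell$Wh + crossprod(cc$Hprev, dz)
    g$cell$b <- g$cell$b + colSums(dz)
    dU <- dz %*% t(params$cell$Wx)
    step_g <- encode_backward(params, seqs$steps[[t]], dU)
    enc_grads <- accumulate_grads(enc_grads, step_g)
    dH <- dz %*% t(params$cell$Wh)
    dC <- dCt * cc$f
  }
  if (!is.null(enc_grads$emb)) g$emb <- enc_grads$emb
  if (!is.null(enc_grads$demo)) g$demo <- enc_grads$demo
  g
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  walk <- function(a, b) {
    if (is.list(a)) Map(walk, a, b) else a + b
  }
  walk(acc, g)
}

subset_seqs <- function(seqs, idx) {
  list(steps = lapply(seqs$steps, subset_input, idx = idx),
       mask = seqs$mask[idx, , drop = FALSE],
       y = seqs$y[idx, , drop = FALSE])
}

lstm_train <- function(params, seqs, val_seqs = NULL,
                       epochs = 30L, batch_size = 128L, lr = 1e-3,
                       pos_weight = 1, patience = 5L, seed = 1L) {
  n <- nrow(seqs$mask)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        bs <- subset_seqs(seqs, idx)
        fwd <- lstm_forward(params, bs, keep_cache = TRUE)
        if (!is.finite(lstm_loss(fwd$p, bs, pos_weight))) {
          stop("NaN loss; trial aborted")
        }
        grads <- lstm_backward(params, bs, fwd, pos_weight)
        upd <- adam_step(params, grads, opt, lr = lr)
        params <- upd$params
        opt <- upd$state
      }
      ref <- if (is.null(val_seqs)) seqs else val_seqs
      vloss <- lstm_loss(lstm_forward(params, ref)$p, ref, pos_weight)
      history <- c(history, vloss)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  list(params = best$params, val_loss = best$loss, history = history)
}
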