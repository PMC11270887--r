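test_that("the default dimension is the rounded-up fourth root of k", {
  expect_identical(default_dim(2), 2L)
  expect_identical(default_dim(1), 1L)
  expect_identical(default_dim(16), 2L)
  expect_identical(default_dim(17), 3L)
  expect_error(default_dim(0), "k must be")
})

test_that("conditional scaling: missing selects a row, observed scales a row", {
  spec <- embedding_spec("x", k = 2, d = 3, center = 0, scale = 1, seed = 4)
  w_obs <- spec$W["observed", ]
  w_mis <- spec$W["missing", ]
  expect_equal(embed_variable(spec, 0), c(0, 0, 0))     # x = 0 -> zero vector
  expect_equal(embed_variable(spec, 2), 2 * w_obs)      # exact scaling
  expect_equal(embed_variable(spec, NA), w_mis)         # state row, value-free
  expect_error(embed_variable(spec, Inf), "finite")
})

test_that("embed_record concatenates per-lab embeddings plus pass-through columns", {
  coh <- small_cohort(50, seed = 3)
  enc <- missingness_encoder(coh, d = 2)
  Z <- cbind(a = coh$age, b = as.numeric(coh$sex == "Male"),
             c = coh$block_index)
  E <- embed_record(enc, coh, passthrough = Z)
  expect_equal(ncol(E), 12 * 2 + 3)
  expect_equal(E[, 25:27], Z, ignore_attr = TRUE)

  # locality: flipping one lab's missingness only moves that lab's block
  row <- coh[3, , drop = FALSE]
  row2 <- row
  row2$lactate <- if (is.na(row$lactate)) 1.0 else NA
  d1 <- embed_record(enc, row)
  d2 <- embed_record(enc, row2)
  changed <- which(d1 != d2)
  lac_cols <- grep("^lactate_e", colnames(d1))
  expect_true(all(changed %in% lac_cols))
  expect_true(length(changed) > 0)
})

test_that("a missing entry embeds identically whatever value might have been there", {
  spec <- embedding_spec("x", seed = 1)
  expect_identical(embed_variable(spec, NA), spec$W["missing", ])
})

test_that("categorical embeddings give one learned row per level and a reserved other", {
  emb <- categorical_embedding(c("Female", "Male"), d = 2, seed = 2)
  a <- embed_categorical(emb, c("Female", "Male", "Female"))
  expect_false(isTRUE(all.equal(a[1, ], a[2, ])))
  expect_identical(a[1, ], a[3, ])
  expect_warning(b <- embed_categorical(emb, "Nonbinary"), "other")
  expect_identical(drop(b), emb$W["(other)", ])
})

test_that("encoder weights survive a JSON round-trip bit-identically", {
  coh <- small_cohort(60, seed = 5)
  enc <- missingness_encoder(coh, d = 2, seed = 9)
  path <- tempfile(fileext = ".json")
  encoder_to_json(enc, path)
  enc2 <- encoder_from_json(path)
  expect_identical(embed_record(enc2, coh), embed_record(enc, coh))
})

test_that("analytic MLP gradients match numerical differentiation", {
  set.seed(3)
  n <- 7; p <- 3; d <- 2; q <- 2
  input <- list(Xz = matrix(rnorm(n * p), n, p),
                M = matrix(rbinom(n * p, 1, 0.4), n, p),
                Z = matrix(rnorm(n * q), n, q))
  input$Xz[input$M == 1] <- 0
  y <- rbinom(n, 1, 0.5)
  emb <- list(obs = matrix(rnorm(p * d, 0, 0.3), p, d),
              mis = matrix(rnorm(p * d, 0, 0.3), p, d))
  params <- informiss:::mlp_init(p * d + q, hidden = 4L, seed = 2, emb = emb)
  fwd <- informiss:::mlp_forward(params, input)
  gr <- informiss:::mlp_backward(params, input, fwd, y)
  loss_at <- function(pp) {
    informiss:::bce_loss(informiss:::mlp_forward(pp, input)$p, y)
  }
  eps <- 1e-6
  num_grad <- function(get, set) {
    p0 <- get(params)
    g <- array(0, dim = dim(as.matrix(p0)))
    for (i in seq_along(p0)) {
      up <- params; a <- get(up); a[i] <- a[i] + eps; up <- set(up, a)
      dn <- params; b <- get(dn); b[i] <- b[i] - eps; dn <- set(dn, b)
      g[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    g
  }
  expect_lt(max(abs(num_grad(function(p) p$layers[[1]]$W,
                             function(p, v) { p$layers[[1]]$W <- v; p }) -
                    gr$layers[[1]]$W)), 1e-6)
  expect_lt(max(abs(num_grad(function(p) p$emb$obs,
                             function(p, v) { p$emb$obs <- v; p }) -
                    gr$emb$obs)), 1e-6)
  expect_lt(max(abs(num_grad(function(p) p$emb$mis,
                             function(p, v) { p$emb$mis <- v; p }) -
                    gr$emb$mis)), 1e-6)
})

test_that("training moves only embedding rows whose state occurs; encoder needs no imputation", {
  # toy task where missingness of one lab perfectly predicts the label
  set.seed(8)
  n <- 400
  miss <- rep(c(TRUE, FALSE), n / 2)
  coh <- toy_cohort(list(l1 = ifelse(miss, NA, rnorm(n)),
                         l2 = rnorm(n)),          # l2 fully observed
                    patient_id = seq_len(n))
  coh$outcome <- as.integer(miss)
  coh$age <- 50; coh$sex <- factor(rep("Female", n))

  m <- fit_mlp(coh, labs = toy_labs(), lab_mode = "embedding",
               config = classifier_config(hidden = 4L, epochs = 1L,
                                          dropout = 0, seed = 1L),
               val_fraction = 0.1)
  init <- informiss:::make_emb_params(m$spec, m$emb_d, 1L)
  # l1's missing row trained; l2 never missing, so its missing row is inert
  expect_gt(max(abs(m$params$emb$mis["l1", ] - init$mis["l1", ])), 0)
  expect_equal(m$params$emb$mis["l2", ], init$mis["l2", ])

  # raw incomplete data scored directly, no imputation step
  expect_true(all(is.finite(predict(m, coh))))
})
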