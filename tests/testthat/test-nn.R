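# Engine-level checks: the layer algebra against independent oracles and
# finite differences, and the architectural contracts of the encoder.

test_that("scaled dot-product attention matches a brute-force loop oracle", {
  set.seed(1)
  for (rep in 1:20) {
    Tn <- sample(2:5, 1); m <- sample(1:4, 1); d <- sample(2:6, 1)
    Q <- matrix(rnorm(Tn * d), Tn, d)
    K <- matrix(rnorm(m * d), m, d)
    V <- matrix(rnorm(m * 3), m, 3)
    att <- scaled_dot_attention(Q, K, V, d = d)
    # loop oracle
    out <- matrix(0, Tn, 3)
    W <- matrix(0, Tn, m)
    for (i in seq_len(Tn)) {
      s <- numeric(m)
      for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
      w <- exp(s) / sum(exp(s))
      W[i, ] <- w
      for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
    }
    expect_equal(att$out, out, tolerance = 1e-6)
    expect_equal(rowSums(att$weights), rep(1, Tn), tolerance = 1e-6)
    expect_equal(att$weights, W, tolerance = 1e-6)
  }
})

test_that("attention degenerates as the algebra dictates", {
  Q <- matrix(rnorm(8), 2, 4)
  K1 <- matrix(rnorm(4), 1, 4); V1 <- matrix(c(3, -1, 2), 1, 3)
  att1 <- scaled_dot_attention(Q, K1, V1)
  expect_equal(att1$weights, matrix(1, 2, 1))       # singleton softmax == 1
  expect_equal(att1$out, rbind(V1[1, ], V1[1, ]))
  K2 <- rbind(K1, K1); V2 <- matrix(rnorm(6), 2, 3) # identical keys
  att2 <- scaled_dot_attention(Q, K2, V2)
  expect_equal(att2$weights, matrix(0.5, 2, 2))
  expect_error(scaled_dot_attention(Q, K1, V1, d = 0), "positive")
})

test_that("attention fusion is equivariant to clinical token permutation", {
  enc <- build_encoder(encoder_config(1 / 16), seed = 2)
  model <- build_fusion_model(enc, 4, fusion_config(d_attn = 8), seed = 3)
  tokens <- matrix(rnorm(8 * enc$cfg$d_model), 8)
  emb <- rnorm(64)
  f1 <- cross_attention_fuse(tokens, emb, model)
  # permute the 8 clinical tokens together with their K/V source rows
  perm <- sample(8)
  emb_p <- as.vector(t(matrix(emb, 8, 8, byrow = TRUE)[perm, ]))
  f2 <- cross_attention_fuse(tokens, emb_p, model)
  expect_equal(f1$fused, f2$fused, tolerance = 1e-10)
})

test_that("classification head follows the sigmoid closed form", {
  expect_equal(classify_fused(rnorm(4), rep(0, 4), 0), 0.5)
  expect_gt(classify_fused(rnorm(4), rep(0, 4), 20), 0.999999)
  set.seed(6)
  for (rep in 1:20) {
    f <- rnorm(5); W <- rnorm(5); b <- rnorm(1)
    expect_equal(classify_fused(f, W, b),
                 1 / (1 + exp(-(sum(W * f) + b))), tolerance = 1e-9)
  }
})

test_that("BCE matches its closed forms and an element-wise oracle", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-5)
  expect_gte(bce_loss(0, 0.999), 0)
  set.seed(7)
  for (rep in 1:20) {
    y <- rbinom(16, 1, 0.4)
    p <- runif(16, 0.01, 0.99)
    w <- runif(16, 0.5, 2)
    acc <- 0
    for (i in 1:16) acc <- acc - w[i] * (y[i] * log(p[i]) +
                                           (1 - y[i]) * log(1 - p[i]))
    expect_equal(bce_loss(y, p, weights = w), acc / 16, tolerance = 1e-9)
  }
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_error(bce_loss(c(1, 2), c(0.5, 0.5)), "binary")
})

test_that("encoder emits the contracted token grid and behaves on batches", {
  enc <- build_encoder(encoder_config(1 / 16), seed = 4)
  x0 <- array(0, c(32, 32, 32, 3))
  pooled <- encode_image(x0, enc, output = "pooled")
  expect_true(all(is.finite(pooled)))          # zero input stays finite
  # 32x reduction: 32^3 -> 1 token, 64^3 -> 8 tokens
  expect_equal(nrow(encode_image(x0, enc, output = "tokens")[[1]]), 1)
  x64 <- array(rnorm(64^3 * 3), c(64, 64, 64, 3))
  expect_equal(nrow(encode_image(x64, enc, output = "tokens")[[1]]), 8)
  expect_error(encode_image(array(0, c(32, 32, 32, 2)), enc), "channels")
  # batch equivariance: permuting inputs permutes outputs
  xs <- lapply(1:3, function(i) array(rnorm(32^3 * 3), c(32, 32, 32, 3)))
  p1 <- encode_image(xs, enc, output = "pooled")
  p2 <- encode_image(xs[c(3, 1, 2)], enc, output = "pooled")
  expect_equal(p1[c(3, 1, 2), ], p2, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the tiny width configuration shrinks parameters > 50-fold", {
  tiny <- build_encoder(encoder_config(1 / 8), seed = 1)
  full <- build_encoder(encoder_config(1), seed = 1)
  n_tiny <- pvl_ns$count_params(tiny$layers)
  n_full <- pvl_ns$count_params(full$layers)
  expect_gt(n_full / n_tiny, 50)
})

test_that("clinical encoder is 64-dimensional, deterministic and robust", {
  enc <- build_encoder(encoder_config(1 / 16), seed = 2)
  model <- build_fusion_model(enc, 6, seed = 9)
  x <- rnorm(6)
  e1 <- encode_clinical(model, x)
  expect_equal(ncol(e1), 64)
  expect_identical(e1, encode_clinical(model, x))
  expect_true(all(is.finite(encode_clinical(model, rep(10, 6)))))
  expect_true(all(is.finite(encode_clinical(model, rep(-10, 6)))))
  expect_error(encode_clinical(model, rnorm(4)), "covariates")
})

test_that("full model gradients match finite differences in every branch", {
  set.seed(10)
  enc <- build_encoder(encoder_config(1 / 16), seed = 7)
  model <- build_fusion_model(enc, 5, fusion_config(d_attn = 8), seed = 11)
  patches <- lapply(1:2, function(i) array(rnorm(16^3 * 3, sd = 0.5),
                                           c(16, 16, 16, 3)))
  clin <- matrix(rnorm(10), 2, 5)
  y <- c(1, 0)
  loss_fn <- function() {
    f <- pvl_ns$fusion_forward(model, patches, clin, training = TRUE)
    bce_loss(y, f$p)
  }
  f <- pvl_ns$fusion_forward(model, patches, clin, training = TRUE)
  b <- pvl_ns$fusion_backward(model, f$cache,
                              pvl_ns$bce_logit_grad(y, f$p))
  flat <- pvl_ns$flatten_grads(b$grads)
  refs <- pvl_ns$fusion_param_refs(model)
  groups <- c("encoder.stem_conv.W", "encoder.s2_b1.conv1.W",
              "encoder.s3_b1.down_conv.W", "encoder.s4_b2.bn2.gamma",
              "clin.fc1.W", "attn.Wq", "attn.Wk", "attn.Wv",
              "head.W", "head.b")
  eps <- 1e-5
  for (g in groups) {
    r <- refs[[g]]
    p <- get(r$field, envir = r$env)
    for (k in sample(length(p), min(2, length(p)))) {
      p0 <- p[k]
      assign(r$field, replace(p, k, p0 + eps), envir = r$env)
      lp <- loss_fn()
      assign(r$field, replace(p, k, p0 - eps), envir = r$env)
      lm <- loss_fn()
      assign(r$field, p, envir = r$env)
      num <- (lp - lm) / (2 * eps)
      expect_equal(flat[[g]][k], num, tolerance = 5e-3,
                   label = paste("grad", g))
    }
  }
  # no dead branch: every parameter group receives nonzero gradient
  nonzero <- vapply(flat, function(g) any(abs(g) > 0), logical(1))
  expect_true(all(nonzero))
})

test_that("untrained model is near chance and the clinical branch is live", {
  enc <- build_encoder(encoder_config(1 / 16), seed = 21)
  model <- build_fusion_model(enc, 5, fusion_config(d_attn = 8), seed = 22)
  set.seed(23)
  patches <- lapply(1:8, function(i) array(runif(16^3 * 3), c(16, 16, 16, 3)))
  clin <- matrix(rnorm(40), 8, 5)
  f <- pvl_ns$fusion_forward(model, patches, clin, training = FALSE)
  expect_lt(abs(mean(f$p) - 0.5), 0.25)
  # zeroing the clinical covariates changes the prediction (fusion active)
  f0 <- pvl_ns$fusion_forward(model, patches, clin * 0, training = FALSE)
  expect_false(isTRUE(all.equal(f$p, f0$p)))
})

test_that("checkpoints round-trip the full parameter state", {
  enc <- build_encoder(encoder_config(1 / 16), seed = 31)
  model <- build_fusion_model(enc, 4, fusion_config(d_attn = 8), seed = 32)
  x <- list(array(rnorm(16^3 * 3), c(16, 16, 16, 3)))
  clin <- matrix(rnorm(4), 1, 4)
  p_before <- pvl_ns$fusion_forward(model, x, clin, training = FALSE)$p
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(model, ck)
  expect_true(file.exists(paste0(ck, ".json")))
  m2 <- load_checkpoint(ck)
  p_after <- pvl_ns$fusion_forward(m2, x, clin, training = FALSE)$p
  expect_equal(p_before, p_after, tolerance = 1e-12)
})
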