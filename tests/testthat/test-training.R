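test_that("log-target standardization matches its definitional oracles", {
  # two distinct values standardize to -1/+1 under the population SD
  z <- standardize_log_target(c(10, 400))
  expect_equal(as.numeric(z), c(-1, 1))
  # applying the transform to the reference set gives mean 0, sd 1
  set.seed(1)
  v <- exp(rnorm(50, 6, 1))
  z <- standardize_log_target(v)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(as.numeric(z)^2)), 1, tolerance = 1e-9)
  # round trip
  back <- inverse_log_target(z, attr(z, "stats"))
  expect_equal(back, v, tolerance = 1e-6)
  # reference-set statistics are used for new values
  z2 <- standardize_log_target(c(5, 50), reference = v)
  expect_equal(as.numeric(z2),
               (log1p(c(5, 50)) - attr(z, "stats")["mean"]) /
                 attr(z, "stats")["sd"],
               ignore_attr = TRUE)
  expect_error(standardize_log_target(c(3, 3, 3)), "zero variance")
  expect_error(standardize_log_target(c(-1, 2)), ">= 0")
})

test_that("stratified folds give exact event balance on the reference cohort", {
  y <- rep(c(1, 0), c(35, 175))
  plan <- make_stratified_folds(y, k = 5, seed = 3)
  for (f in 1:5) {
    va <- plan$validation[[f]]
    expect_length(va, 42)
    expect_equal(sum(y[va]), 7)
  }
  # partition: folds are disjoint and cover the cohort
  expect_setequal(unlist(plan$validation), seq_along(y))
  expect_equal(sum(lengths(plan$validation)), length(y))
  # n = 10 with 5 events: one of each per fold
  y10 <- rep(c(1, 0), 5)
  p10 <- make_stratified_folds(y10, k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(y10[p10$validation[[f]]]), 1)
    expect_length(p10$validation[[f]], 2)
  }
  # reproducible per seed; different across seeds
  expect_identical(plan$fold, make_stratified_folds(y, 5, seed = 3)$fold)
  expect_false(identical(plan$fold, make_stratified_folds(y, 5, seed = 4)$fold))
  expect_error(make_stratified_folds(rep(c(1, 0), c(3, 50)), k = 5),
               "stratified")
  expect_match(fold_plan_digest(plan), "^k5\\|")
})

test_that("binarize applies the >= tie rule and the extremes", {
  expect_equal(binarize(0.5, 0.5), 1L)
  expect_equal(binarize(c(0.2, 0.8), 0), c(1L, 1L))
  expect_equal(binarize(c(0.2, 0.8), 1.01), c(0L, 0L))
  p <- runif(50)
  y <- rbinom(50, 1, 0.3)
  for (t in c(0.2, 0.5, 0.9)) {
    pred <- binarize(p, t)
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    expect_equal(tp + fp + tn + fn, 50)
  }
})

test_that("the pretrain-set constructor is a leakage firewall", {
  vols <- lapply(1:4, function(i) array(0, c(8, 8, 8, 3)))
  ok <- pretrain_set(vols, c(10, 20, 30, 40))
  expect_s3_class(ok, "pvl_pretrain_set")
  expect_error(pretrain_set(vols, data.frame(v = 1:4, y = c(0, 1, 0, 1))),
               "refused")
  labelled <- c(pvl_ge_moderate = 10, a = 20, b = 30, c = 40)
  expect_error(pretrain_set(vols, labelled), "outcome")
  expect_error(stage1_pretrain(list(volumes = vols)), "firewall")
  expect_error(pretrain_set(vols, c(1, 2, 3)), "one calcification volume")
})

test_that("per-fold covariate standardization uses training rows only", {
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("a", "b")
  tr <- 1:12
  # inject sentinel values into the held-out rows: training statistics must
  # be unaffected, and the sentinels must map through the training stats
  X[13, 1] <- 1e6
  Xs <- pvl_ns$standardize_covariates(X, tr)
  expect_equal(mean(Xs[tr, 1]), 0, tolerance = 1e-9)
  expect_equal(sd(Xs[tr, 1]), 1, tolerance = 1e-9)
  st <- attr(Xs, "standardization")[[1]]
  expect_equal(unname(Xs[13, 1]), (1e6 - st[["mean"]]) / st[["sd"]])
  expect_gt(Xs[13, 1], 1e4)   # sentinel visibly out of the training scale
  # binary columns pass through untouched
  Xb <- cbind(X, bin = rbinom(20, 1, 0.5))
  Xbs <- pvl_ns$standardize_covariates(Xb, tr)
  expect_equal(Xbs[, "bin"], Xb[, "bin"])
})

test_that("stage-1 pretraining solves a degenerate regression exactly-ish", {
  # constant target: best achievable MSE ~ 0, model predicts the constant
  set.seed(5)
  vols <- lapply(1:8, function(i) array(runif(8^3 * 3), c(8, 8, 8, 3)))
  pset <- pretrain_set(vols, rep(c(100, 100.0001), 4))
  cfg <- stage1_config(lr = 1e-2, max_epochs = 8, batch_size = 4, seed = 2)
  fit <- stage1_pretrain(pset, cfg, encoder_config(1 / 16),
                         augment_config(crop_size = 8,
                                        intensity_shift_prob = 0))
  pred <- pvl_ns$stage1_predict(fit$encoder, fit$head, vols, 8L)
  expect_lt(mean(pred^2), 0.5)  # z-targets are ~0; predictions move there
  expect_true(all(diff(fit$history$epoch) == 1))
  expect_lte(fit$best_epoch, max(fit$history$epoch))
})

test_that("stage-1 runs are bit-reproducible for a fixed seed", {
  set.seed(6)
  vols <- lapply(1:6, function(i) array(runif(8^3 * 3), c(8, 8, 8, 3)))
  targets <- exp(runif(6, 3, 7))
  cfg <- stage1_config(lr = 1e-3, max_epochs = 3, batch_size = 2, seed = 9)
  aug <- augment_config(crop_size = 8)
  f1 <- stage1_pretrain(pretrain_set(vols, targets), cfg,
                        encoder_config(1 / 16), aug)
  f2 <- stage1_pretrain(pretrain_set(vols, targets), cfg,
                        encoder_config(1 / 16), aug)
  expect_identical(f1$history, f2$history)
})

test_that("stage-2 produces exactly one out-of-fold prediction per patient", {
  # miniature end-to-end run: 20 patients, 8^3 volumes, 2 epochs
  set.seed(30)
  n <- 20
  y <- rep(c(1, 0), c(8, 12))
  vols <- lapply(seq_len(n), function(i) {
    v <- array(runif(8^3 * 3), c(8, 8, 8, 3))
    v[, , , 3] <- round(v[, , , 3] * 0.4 + y[i] * 0.45)
    v
  })
  clinical <- data.frame(patient_id = sprintf("P%02d", 1:n),
                         x1 = rnorm(n) + 2 * y, x2 = rnorm(n),
                         pvl_ge_moderate = y)
  enc <- build_encoder(encoder_config(1 / 16), seed = 40)
  cfg <- stage2_config(lr = 1e-3, max_epochs = 2, k_folds = 4,
                       early_stop_patience = 1, scheduler_patience = 1,
                       batch_size = 4, seed = 50)
  run <- stage2_finetune(vols, clinical, enc, cfg,
                         fusion_config(d_attn = 8),
                         augment_config(crop_size = 8))
  ps <- run$predictions
  expect_equal(nrow(ps), n)
  expect_equal(anyDuplicated(ps$patient_id), 0)
  expect_true(all(ps$p >= 0 & ps$p <= 1))
  expect_equal(sort(unique(ps$fold)), 1:4)
  # no patient appears in two validation folds
  expect_equal(sum(lengths(run$fold_plan$validation)), n)
  # learning-rate schedule never increases
  for (h in run$history) expect_true(all(diff(h$lr) <= 0))
  # single-class training split is refused
  bad <- clinical; bad$pvl_ge_moderate <- rep(c(1, 0), c(4, 16))
  plan_bad <- list(fold = rep(1:4, each = 5), k = 4L,
                   labels = bad$pvl_ge_moderate,
                   validation = split(1:20, rep(1:4, each = 5)),
                   train = lapply(1:4, function(f) which(rep(1:4, each = 5) != f)))
  class(plan_bad) <- "pvl_fold_plan"
  expect_error(stage2_finetune(vols, bad, enc, cfg,
                               fusion_config(d_attn = 8),
                               augment_config(crop_size = 8),
                               folds = plan_bad),
               "single outcome class")
})
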