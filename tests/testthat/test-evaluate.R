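test_that("AUC equals the pairwise concordance oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(1)
  y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(y, rnorm(4000)) - 0.5), 0.03)
  for (rep in 1:20) {
    n <- 30
    y <- c(1, 0, rbinom(n - 2, 1, 0.3))
    s <- sample(seq(0.1, 1, 0.1), n, replace = TRUE)  # ties on purpose
    pos <- s[y == 1]; neg <- s[y == 0]
    acc <- 0
    for (a in pos) for (b in neg) acc <- acc + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(y, s), acc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("confusion metrics match hand counts and report NA when undefined", {
  y <- c(1, 1, 0, 0, 0)
  expect_equal(unname(confusion_metrics(y, y)), rep(1, 5))
  # all-negative predictions at prevalence pi
  m <- confusion_metrics(y, rep(0, 5))
  expect_equal(m[["sensitivity"]], 0)
  expect_equal(m[["specificity"]], 1)
  expect_equal(m[["npv"]], 1 - 0.4)
  expect_true(is.na(m[["ppv"]]))   # zero denominator -> NA, never 0
  set.seed(2)
  for (rep in 1:20) {
    y <- rbinom(40, 1, 0.4); p <- rbinom(40, 1, 0.5)
    tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
    m <- confusion_metrics(y, p)
    expect_equal(m[["accuracy"]], (tp + tn) / 40)
    if (tp + fn > 0) expect_equal(m[["sensitivity"]], tp / (tp + fn))
    if (tp + fp > 0) expect_equal(m[["ppv"]], tp / (tp + fp))
  }
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("fold aggregation reproduces the published CI arithmetic", {
  # mean 0.822, SD 0.114, k = 5 under the t-on-SEM convention
  folds_b <- c(0.708, 0.936, 0.822, 0.936, 0.708)  # mean .822, sd .114
  expect_equal(sd(folds_b), 0.114, tolerance = 1e-3)
  agg_b <- aggregate_folds(folds_b, convention = "t_sem")
  expect_equal(round(agg_b$ci_lo, 3), 0.680)
  expect_equal(round(agg_b$ci_hi, 3), 0.964)
  # mean 0.694, SD 0.050 under the normal-on-SD convention
  folds_a <- c(0.644, 0.744, 0.694, 0.744, 0.644)
  agg_a <- aggregate_folds(folds_a, convention = "normal_sd")
  expect_equal(round(agg_a$ci_lo, 3), 0.596)
  expect_equal(round(agg_a$ci_hi, 3), 0.792)
  # SD 0 -> point interval; truncation to [0, 1]
  z <- aggregate_folds(rep(0.7, 5))
  expect_equal(z$ci_lo, 0.7); expect_equal(z$ci_hi, 0.7)
  hi <- aggregate_folds(c(0.95, 0.99, 0.97, 0.90, 1.0),
                        convention = "normal_sd")
  expect_lte(hi$ci_hi, 1)
  expect_error(aggregate_folds(0.5), "k >= 2")
})

test_that("DeLong variance matches the direct structural-components loop", {
  set.seed(3)
  n <- 20
  y <- rep(c(1, 0), c(8, 12))
  sa <- rnorm(n) + y; sb <- rnorm(n) + 0.5 * y
  res <- delong_test(sa, sb, y)
  # direct loop implementation of the components
  pos <- which(y == 1); neg <- which(y == 0)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  comp <- function(s) {
    v10 <- sapply(pos, function(i) mean(sapply(neg, function(j) psi(s[i], s[j]))))
    v01 <- sapply(neg, function(j) mean(sapply(pos, function(i) psi(s[i], s[j]))))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  ca <- comp(sa); cb <- comp(sb)
  v <- (var(ca$v10) + var(cb$v10) - 2 * cov(ca$v10, cb$v10)) / length(pos) +
    (var(ca$v01) + var(cb$v01) - 2 * cov(ca$v01, cb$v01)) / length(neg)
  expect_equal(res$var_diff, v, tolerance = 1e-12)
  expect_equal(res$auc_a, ca$auc, tolerance = 1e-12)
  # identical scores -> zero difference, p = 1
  same <- delong_test(sa, sa, y)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(sa, sb, rep(0, n)), "both classes")
})

test_that("DeLong p agrees with a paired-bootstrap oracle on n = 40", {
  set.seed(4)
  n <- 40
  y <- rep(c(1, 0), c(14, 26))
  sa <- rnorm(n) + 1.1 * y
  sb <- rnorm(n) + 0.4 * y
  res <- delong_test(sa, sb, y)
  # paired bootstrap of the AUC difference; p from the normal quantile of
  # the observed difference against the bootstrap spread
  B <- 20000
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) { diffs[b] <- NA; next }
    diffs[b] <- roc_auc(y[idx], sa[idx]) - roc_auc(y[idx], sb[idx])
  }
  diffs <- diffs[!is.na(diffs)]
  p_boot <- 2 * pnorm(-abs(mean(diffs)) / sd(diffs))
  expect_lt(abs(res$p_value - p_boot), 0.02)
})

test_that("Brier score honours its analytic benchmarks", {
  # constant prediction at prevalence: pi (1 - pi); 35/210 -> 0.139
  y <- rep(c(1, 0), c(35, 175))
  ps <- data.frame(y = y, p = rep(mean(y), length(y)))
  b <- brier_and_calibration(ps)
  expect_equal(b$brier, (35 / 210) * (1 - 35 / 210), tolerance = 1e-12)
  expect_equal(round(b$brier, 3), 0.139)
  expect_equal(brier_and_calibration(data.frame(y = y, p = y))$brier, 0)
  set.seed(5)
  y <- rbinom(50, 1, 0.3); p <- runif(50)
  acc <- 0
  for (i in 1:50) acc <- acc + (p[i] - y[i])^2
  expect_equal(brier_and_calibration(data.frame(y = y, p = p))$brier,
               acc / 50, tolerance = 1e-12)
})

test_that("calibration bins partition [0,1] and count every prediction", {
  set.seed(6)
  y <- rbinom(200, 1, 0.2); p <- runif(200)
  cal <- brier_and_calibration(data.frame(y = y, p = p), n_bins = 10)
  expect_equal(sum(cal$curve$n), 200)
  expect_equal(cal$curve$lo, seq(0, 0.9, 0.1))
  expect_equal(cal$curve$hi, seq(0.1, 1, 0.1))
  # per-bin observed rate equals the hand count
  sel <- p >= 0.3 & p < 0.4
  expect_equal(cal$curve$observed_rate[4], mean(y[sel]))
  # empty bins reported with count 0 and NA coordinates
  cal2 <- brier_and_calibration(data.frame(y = c(0, 1), p = c(0.05, 0.06)))
  expect_equal(cal2$curve$n[5], 0)
  expect_true(is.na(cal2$curve$mean_predicted[5]))
})

test_that("decision-curve net benefit matches its closed forms", {
  set.seed(7)
  y <- rbinom(120, 1, 0.25); p <- runif(120)
  dc <- decision_curve(data.frame(y = y, p = p))
  prev <- mean(y)
  expect_equal(dc$treat_all,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  expect_true(all(dc$treat_none == 0))
  # perfect model: net benefit = prevalence at every threshold
  dcp <- decision_curve(data.frame(y = y, p = y))
  expect_equal(dcp$net_benefit, rep(prev, nrow(dcp)))
  # hand count at t = 0.25: NB = TP/n - FP/(3n)
  t <- 0.25
  tp <- sum(p >= t & y == 1); fp <- sum(p >= t & y == 0)
  expect_equal(dc$net_benefit[dc$threshold == t], tp / 120 - fp / (3 * 120))
  expect_equal(range(dc$threshold), c(0.01, 0.80))
  expect_error(decision_curve(data.frame(y = y, p = p), thresholds = c(0, 1)),
               "inside")
})

test_that("the contingency engine reproduces the printed descriptive table", {
  # counts from the published cohort table: group x trait
  sex <- matrix(c(27, 9, 201, 165), 2, 2, byrow = TRUE)    # p = 0.032
  htn <- matrix(c(9, 27, 114, 252), 2, 2, byrow = TRUE)    # p = 0.566
  cad <- matrix(c(6, 30, 89, 277), 2, 2, byrow = TRUE)     # p = 0.409
  expect_equal(round(contingency_test(t(sex))$p_value, 3), 0.032)
  expect_equal(round(contingency_test(t(htn))$p_value, 3), 0.566)
  expect_equal(round(contingency_test(t(cad))$p_value, 3), 0.409)
  expect_identical(contingency_test(t(sex))$test, "chisq_yates")
  # small expected counts route to Fisher (atrial-fibrillation-like row)
  small <- matrix(c(5, 31, 30, 336), 2, 2, byrow = TRUE)
  expect_identical(contingency_test(t(small))$test, "fisher")
  # identical balanced groups -> Fisher p = 1
  expect_equal(contingency_test(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("cohort table tests dispatch by variable type", {
  set.seed(8)
  n <- 80
  tab <- data.frame(patient_id = 1:n,
                    age = rnorm(n, 70, 8),
                    flag = rbinom(n, 1, 0.4),
                    pvl_ge_moderate = rbinom(n, 1, 0.3))
  res <- cohort_table_tests(tab)
  expect_equal(res$type[res$variable == "age"], "continuous")
  expect_equal(res$test[res$variable == "age"], "wilcoxon")
  expect_equal(res$type[res$variable == "flag"], "binary")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # wilcoxon agrees with the base implementation
  pw <- wilcox.test(age ~ pvl_ge_moderate, data = tab, exact = FALSE,
                    correct = TRUE)$p.value
  expect_equal(res$p_value[res$variable == "age"], pw)
  expect_error(cohort_table_tests(tab, group = "age"), "binary")
})

test_that("fold_metrics assembles per-fold rows ready for aggregation", {
  set.seed(9)
  ps <- data.frame(fold = rep(1:5, each = 20),
                   y = rbinom(100, 1, 0.3),
                   p = runif(100))
  fm <- fold_metrics(ps)
  expect_equal(nrow(fm), 5)
  expect_named(fm, c("fold", "auc", "accuracy", "sensitivity",
                     "specificity", "ppv", "npv"))
  agg <- aggregate_folds(as.matrix(fm[, -1]))
  expect_equal(nrow(agg), 6)
  expect_true(all(agg$ci_lo <= agg$mean & agg$mean <= agg$ci_hi, na.rm = TRUE))
})
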