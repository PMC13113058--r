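# ---------------------------------------------------------------------------
# Evaluation harness: discrimination metrics with fold aggregation and CIs,
# the DeLong comparison of correlated AUCs, calibration + Brier score,
# decision-curve analysis, and the descriptive-table tests.
# ---------------------------------------------------------------------------

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability with ties counted 1/2, computed from
#' midranks.
#'
#' @param labels binary outcome. @param scores predicted scores.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity, PPV and NPV from binary predictions.
#' Ratios with a zero denominator are reported as `NA` (never silently 0).
#'
#' @param labels true binary labels. @param predicted predicted binary labels.
#' @export
confusion_metrics <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("confusion_metrics: inputs must be binary")
  }
  tp <- sum(labels == 1 & predicted == 1)
  fp <- sum(labels == 0 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fn <- sum(labels == 1 & predicted == 0)
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn))
}

#' Aggregate per-fold metrics into mean, SD and a 95% CI
#'
#' Two CI conventions are implemented because published fold summaries use
#' both: `"normal_sd"` (mean +/- 1.96 * SD, a population-spread convention)
#' and `"t_sem"` (mean +/- t(0.975, k-1) * SD / sqrt(k), a CI for the mean).
#' SD is the sample SD (k-1 denominator); the CI is truncated to [0, 1];
#' `NA` fold metrics (e.g. undefined PPV in an all-negative fold) are
#' dropped with a recorded note.
#'
#' @param per_fold numeric vector (one metric) or data.frame/matrix of fold
#'   metrics (folds x metrics).
#' @param convention CI convention; default `"t_sem"`.
#' @return data.frame with metric, k, mean, sd, ci_lo, ci_hi, n_dropped.
#' @export
aggregate_folds <- function(per_fold, convention = c("t_sem", "normal_sd")) {
  convention <- match.arg(convention)
  if (is.null(dim(per_fold))) per_fold <- matrix(per_fold, ncol = 1,
                                                 dimnames = list(NULL, "metric"))
  per_fold <- as.matrix(per_fold)
  if (nrow(per_fold) < 2) stop("aggregate_folds: need k >= 2 folds")
  out <- lapply(colnames(per_fold), function(nm) {
    v <- per_fold[, nm]
    dropped <- sum(is.na(v))
    v <- v[!is.na(v)]
    k <- length(v)
    m <- mean(v); s <- stats::sd(v)
    half <- switch(convention,
                   normal_sd = 1.96 * s,
                   t_sem = stats::qt(0.975, k - 1) * s / sqrt(k))
    data.frame(metric = nm, k = k, mean = m, sd = s,
               ci_lo = max(0, m - half), ci_hi = min(1, m + half),
               convention = convention, n_dropped = dropped)
  })
  do.call(rbind, out)
}

#' DeLong test for two correlated AUCs
#'
#' Structural-components (jackknife) estimate of the variance of the AUC
#' difference for paired scores, with a two-sided normal p-value.
#'
#' @param scores_a,scores_b paired scores on identical patients.
#' @param labels binary outcome.
#' @return list with `auc_a`, `auc_b`, `diff`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("delong_test: both classes must be present")
  comp <- function(s) {
    # psi(x_i, y_j) = 1, 1/2, 0 for x > y, x == y, x < y
    M <- outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(M), v10 = rowMeans(M), v01 = colMeans(M))
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, diff = d, var_diff = var_diff,
       z = z, p_value = p)
}

#' Brier score and calibration curve
#'
#' Brier = mean squared (p - y) over the pooled out-of-fold predictions.
#' Calibration bins are uniform on [0, 1]; empty bins are reported with
#' count 0 and `NA` coordinates (omitted from a plotted curve).
#'
#' @param predictions data.frame with columns `y` and `p` (a prediction set),
#'   or a list/vector pair via `y`.
#' @param n_bins number of uniform bins.
#' @param y optional label vector when `predictions` is a probability vector.
#' @return list with `brier`, `curve` (bin table), `n_bins`.
#' @export
brier_and_calibration <- function(predictions, n_bins = 10L, y = NULL) {
  if (is.data.frame(predictions)) {
    p <- predictions$p; yy <- predictions$y
  } else {
    p <- as.numeric(predictions); yy <- y
  }
  stopifnot(length(p) == length(yy), all(p >= 0 & p <= 1))
  brier <- mean((p - yy)^2)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(p, edges, rightmost.closed = TRUE), n_bins)
  curve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1],
               n = sum(sel),
               mean_predicted = if (any(sel)) mean(p[sel]) else NA_real_,
               observed_rate = if (any(sel)) mean(yy[sel]) else NA_real_)
  }))
  list(brier = brier, curve = curve, n_bins = n_bins)
}

#' Decision-curve analysis
#'
#' Net benefit of treating at threshold t: `TP/n - FP/n * t/(1-t)` with
#' classification at `p >= t`, against the treat-all
#' (`pi - (1-pi) t/(1-t)`) and treat-none (0) strategies.
#'
#' @param predictions data.frame with `y`, `p`.
#' @param thresholds threshold grid in (0, 1).
#' @return data.frame threshold / net_benefit / treat_all / treat_none.
#' @export
decision_curve <- function(predictions,
                           thresholds = seq(0.01, 0.80, by = 0.01)) {
  p <- predictions$p; y <- predictions$y
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(y); prev <- mean(y)
  out <- lapply(thresholds, function(t) {
    pred <- p >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    data.frame(threshold = t,
               net_benefit = tp / n - fp / n * t / (1 - t),
               treat_all = prev - (1 - prev) * t / (1 - t),
               treat_none = 0)
  })
  do.call(rbind, out)
}

#' Per-fold metric table for a prediction set
#'
#' AUC plus threshold metrics per validation fold, ready for
#' [aggregate_folds()].
#'
#' @param predictions prediction-set data.frame (`fold`, `y`, `p`).
#' @param threshold decision threshold for the confusion metrics.
#' @export
fold_metrics <- function(predictions, threshold = 0.5) {
  folds <- sort(unique(predictions$fold))
  out <- do.call(rbind, lapply(folds, function(f) {
    d <- predictions[predictions$fold == f, ]
    cm <- confusion_metrics(d$y, binarize(d$p, threshold))
    data.frame(fold = f, auc = roc_auc(d$y, d$p), t(cm))
  }))
  out
}

#' Descriptive-table group comparisons
#'
#' Continuous variables: two-sided Wilcoxon rank-sum (normal approximation
#' with tie correction). Binary variables: Yates-corrected chi-square when
#' every expected cell count is >= 5, otherwise Fisher's exact test (the
#' usual "as appropriate" rule).
#'
#' @param data cohort data.frame.
#' @param group name of the binary grouping column (the outcome).
#' @param variables variables to test (default: all others).
#' @return data.frame variable / type / test / p_value.
#' @export
cohort_table_tests <- function(data, group = "pvl_ge_moderate",
                               variables = NULL) {
  g <- data[[group]]
  if (is.null(g)) stop("grouping column not found")
  if (length(unique(g)) != 2) stop("grouping must be binary")
  if (min(table(g)) == 0) stop("empty group")
  variables <- variables %||% setdiff(names(data), c(group, "patient_id"))
  out <- lapply(variables, function(v) {
    x <- data[[v]]
    if (all(x %in% c(0, 1))) {
      tab <- table(factor(g, levels = sort(unique(g), decreasing = TRUE)),
                   factor(x, levels = c(1, 0)))
      res <- contingency_test(tab)
      data.frame(variable = v, type = "binary", test = res$test,
                 p_value = res$p_value)
    } else {
      p <- stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE)$p.value
      data.frame(variable = v, type = "continuous", test = "wilcoxon",
                 p_value = p)
    }
  })
  do.call(rbind, out)
}

#' 2x2 contingency test with the "as appropriate" rule
#'
#' Yates-corrected chi-square when all expected counts are >= 5, otherwise
#' two-sided Fisher's exact test.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has an empty margin")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    list(test = "chisq_yates",
         p_value = stats::chisq.test(counts, correct = TRUE)$p.value)
  } else {
    list(test = "fisher",
         p_value = stats::fisher.test(counts)$p.value)
  }
}
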