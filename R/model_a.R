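# ---------------------------------------------------------------------------
# Model A: the conventional baseline. A 35-feature clinical + manual-CT
# table is fed to five classifiers (L1/L2 logistic via glmnet, single-hidden-
# layer MLP, bagged-tree forest, gradient boosting) with class-balanced
# sample weights; the winner is chosen by cross-validated AUC on the same
# fold plan as Model B.
# ---------------------------------------------------------------------------

#' The 35-feature manifest of the conventional model
#'
#' 26 recorded clinical / anatomical / procedural variables plus 9 derived
#' anatomical indices (effective annular diameters, level-to-level ratios,
#' calcification density, balloon-annulus mismatch and the log calcification
#' volume). The exact composition of the published feature set is not
#' enumerated anywhere; this manifest is the package's documented choice and
#' can be overridden in [assemble_features()].
#'
#' @return character vector of 35 feature names.
#' @export
feature_manifest <- function() {
  c(.clin_continuous, .clin_binary,
    "log_calc_volume", "area_derived_diameter_mm",
    "perimeter_derived_diameter_mm", "annular_eccentricity_index",
    "stj_annulus_ratio", "lvot_annulus_ratio", "asc_stj_ratio",
    "calc_density_mm", "balloon_annulus_mismatch_mm")
}

#' Assemble the Model A feature table
#'
#' Adds the derived anatomical indices to the recorded covariates and
#' validates the result against the manifest (exactly 35 columns, no missing
#' values, binaries coded 0/1).
#'
#' @param clinical cohort clinical table ([generate_cohort()] layout).
#' @param manifest feature names; defaults to [feature_manifest()].
#' @return data.frame with the manifest columns plus `patient_id` and the
#'   outcome.
#' @export
assemble_features <- function(clinical, manifest = feature_manifest()) {
  tab <- clinical
  d_area <- 2 * sqrt(tab$annular_area_mm2 / pi)
  d_perim <- tab$annular_perimeter_mm / pi
  tab$log_calc_volume <- log1p(tab$calc_volume_mm3)
  tab$area_derived_diameter_mm <- d_area
  tab$perimeter_derived_diameter_mm <- d_perim
  tab$annular_eccentricity_index <- d_perim / d_area
  tab$stj_annulus_ratio <- tab$stj_diameter_mm / d_perim
  tab$lvot_annulus_ratio <- tab$lvot_perimeter_mm / tab$annular_perimeter_mm
  tab$asc_stj_ratio <- tab$max_ascending_mm / tab$stj_diameter_mm
  tab$calc_density_mm <- tab$calc_volume_mm3 / tab$annular_area_mm2
  tab$balloon_annulus_mismatch_mm <- tab$post_dilatation_balloon_mm - d_perim
  missing_cols <- setdiff(manifest, names(tab))
  if (length(missing_cols)) {
    stop("feature table does not match the manifest; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tab[, c("patient_id", manifest, "pvl_ge_moderate")]
  if (anyNA(out)) stop("missing values in assembled features")
  if (any(!is.finite(as.matrix(out[, manifest])))) {
    stop("non-finite values in assembled features")
  }
  attr(out, "manifest") <- manifest
  out
}

# class-balanced weights: total weight split evenly between classes
.balanced_weights <- function(y) {
  n <- length(y); n1 <- sum(y); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

# -- the five candidate classifiers -----------------------------------------
# each fit function returns an object with a predict(obj, X) -> probability

.fit_lr <- function(X, y, w, alpha, seed) {
  # stratified inner folds so every inner training set keeps both classes
  foldid <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[sample(idx)] <- rep_len(1:5, length(idx))
    }
    f
  })
  fit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                           weights = w, foldid = foldid,
                           standardize = FALSE)
  list(fit = fit,
       predict = function(obj, Xn) {
         as.numeric(stats::predict(obj$fit, Xn, s = "lambda.min",
                                   type = "response"))
       })
}

.fit_mlp <- function(X, y, w, seed, hidden = 32L, decay = 0.001,
                     max_epochs = 500L, lr = 0.01) {
  with_seed(seed, {
    layers <- list(fc1 = linear_layer(ncol(X), hidden),
                   act = relu_mat_layer(),
                   fc2 = linear_layer(hidden, 1L, init_sd = 1 / sqrt(hidden)))
    refs <- collect_params(layers)
    opt <- adam_state(refs, lr = lr, weight_decay = decay)
    for (epoch in seq_len(max_epochs)) {
      fwd <- seq_forward(layers, X, training = TRUE)
      p <- 1 / (1 + exp(-as.vector(fwd$out)))
      dlogit <- bce_logit_grad(y, p, weights = w)
      bwd <- seq_backward(layers, fwd$caches, matrix(dlogit, ncol = 1))
      names(bwd$grads) <- names(layers)
      opt <- adam_step(opt, flatten_grads(bwd$grads))
    }
    list(layers = layers,
         predict = function(obj, Xn) {
           out <- seq_forward(obj$layers, Xn, training = FALSE)$out
           1 / (1 + exp(-as.vector(out)))
         })
  })
}

.fit_rf <- function(X, y, w, seed, n_trees = 200L, max_leaves = 16L,
                    min_leaf = 5L) {
  with_seed(seed, {
    fit <- fit_forest(X, y, w, n_trees = n_trees, max_leaves = max_leaves,
                      min_leaf = min_leaf)
    list(fit = fit, predict = function(obj, Xn) {
      pmin(pmax(predict_forest(obj$fit, Xn), 1e-6), 1 - 1e-6)
    })
  })
}

.fit_gbm_spec <- function(X, y, w, seed, n_trees = 100L,
                          interaction_depth = 3L, shrinkage = 0.05,
                          bag_fraction = 0.8) {
  with_seed(seed, {
    fit <- fit_gbm(X, y, w, n_trees = n_trees,
                   interaction_depth = interaction_depth,
                   shrinkage = shrinkage, bag_fraction = bag_fraction)
    list(fit = fit, predict = function(obj, Xn) predict_gbm(obj$fit, Xn))
  })
}

#' The five Model A classifier specifications
#'
#' Hyperparameters as fixed a priori in the reference setup: penalized
#' logistic regressions tuned by inner cross-validation, an MLP with one
#' 32-unit hidden layer (L2 decay 0.001, up to 500 epochs), a 200-tree
#' forest with at most 16 terminal nodes and minimum node size 5, and a
#' 100-tree GBM (interaction depth 3, shrinkage 0.05, bag fraction 0.8).
#' Class-balanced sample weights apply to all of them.
#'
#' @export
classifier_specs <- function() {
  list(
    `LR-L1` = function(X, y, w, seed) .fit_lr(X, y, w, alpha = 1, seed),
    `LR-L2` = function(X, y, w, seed) .fit_lr(X, y, w, alpha = 0, seed),
    MLP = function(X, y, w, seed) .fit_mlp(X, y, w, seed),
    RF = function(X, y, w, seed) .fit_rf(X, y, w, seed),
    GBM = function(X, y, w, seed) .fit_gbm_spec(X, y, w, seed)
  )
}

#' Fit the five candidates and select the best by cross-validated AUC
#'
#' Uses the supplied fold plan (the identical plan used by the multi-modal
#' model; identity is asserted on the plan digest when one is provided).
#' Continuous features are standardized with training-fold statistics.
#'
#' @param features table from [assemble_features()].
#' @param folds a `pvl_fold_plan` over the same cohort.
#' @param specs candidate classifiers; defaults to [classifier_specs()].
#' @param seed seed controlling every stochastic fit.
#' @param expected_digest optional fold-plan digest to assert against.
#' @return list with `winner`, `candidate_auc` (per-fold + mean),
#'   `predictions` (winner's out-of-fold set), `all_predictions`.
#' @export
fit_and_select <- function(features, folds, specs = classifier_specs(),
                           seed = 1L, expected_digest = NULL) {
  manifest <- attr(features, "manifest") %||% feature_manifest()
  y <- features$pvl_ge_moderate
  if (!identical(folds$labels, y)) {
    stop("fold plan was built for a different outcome vector")
  }
  if (!is.null(expected_digest) &&
      !identical(fold_plan_digest(folds), expected_digest)) {
    stop("fold plan digest mismatch: Models A and B must share folds")
  }
  X <- as.matrix(features[, manifest])
  n <- nrow(X)
  oof <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, names(specs)))
  auc_folds <- matrix(NA_real_, folds$k, length(specs),
                      dimnames = list(NULL, names(specs)))
  warns <- character()
  for (f in seq_len(folds$k)) {
    tr <- folds$train[[f]]; va <- folds$validation[[f]]
    Xs <- standardize_covariates(X, tr)
    w <- .balanced_weights(y[tr])
    for (ci in seq_along(specs)) {
      fit <- withCallingHandlers(
        specs[[ci]](Xs[tr, , drop = FALSE], y[tr], w, seed + 97L * f + ci),
        warning = function(wn) {
          warns <<- c(warns, sprintf("%s fold %d: %s", names(specs)[ci], f,
                                     conditionMessage(wn)))
          invokeRestart("muffleWarning")
        })
      oof[va, ci] <- fit$predict(fit, Xs[va, , drop = FALSE])
      auc_folds[f, ci] <- roc_auc(y[va], oof[va, ci])
    }
  }
  mean_auc <- colMeans(auc_folds)
  winner <- names(specs)[which.max(mean_auc)]
  predictions <- data.frame(patient_id = features$patient_id,
                            fold = folds$fold, y = y, p = oof[, winner],
                            model = "A", stringsAsFactors = FALSE)
  list(winner = winner,
       candidate_auc = list(per_fold = auc_folds, mean = mean_auc),
       predictions = predictions,
       all_predictions = oof,
       fold_digest = fold_plan_digest(folds),
       warnings = warns)
}
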