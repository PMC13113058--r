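# ---------------------------------------------------------------------------
# Small CART-family learners (no tree package ships with the environment).
# Trees are grown best-first with an explicit max-leaves constraint, exact
# split search over sorted unique values, and case weights throughout.
# Used by the Model A baseline: bagged classification trees ("random
# forest") and bernoulli-deviance gradient boosting.
# ---------------------------------------------------------------------------

# Best split of one node. For classification (criterion = "gini") y is 0/1
# and splits minimize weighted Gini impurity; for boosting
# (criterion = "sse") y is a working response and splits minimize weighted
# squared error. Returns NULL when no admissible split exists.
.best_split <- function(X, y, w, rows, features, min_leaf) {
  best <- NULL
  for (j in features) {
    xv <- X[rows, j]
    ord <- order(xv)
    xs <- xv[ord]; ys <- y[rows][ord]; ws <- w[rows][ord]
    cw <- cumsum(ws); cwy <- cumsum(ws * ys)
    tot_w <- cw[length(cw)]; tot_wy <- cwy[length(cwy)]
    # candidate cut after position i (between distinct values)
    cand <- which(diff(xs) > 0)
    if (!length(cand)) next
    nl <- cumsum(rep(1, length(xs)))[cand]
    nr <- length(xs) - nl
    ok <- nl >= min_leaf & nr >= min_leaf
    if (!any(ok)) next
    cand <- cand[ok]
    wl <- cw[cand]; wyl <- cwy[cand]
    wr <- tot_w - wl; wyr <- tot_wy - wyl
    # weighted SSE of a two-leaf fit == impurity criterion for both cases:
    # for 0/1 y, weighted Gini and weighted SSE rank splits identically.
    score <- -(wyl^2 / wl + wyr^2 / wr)
    i <- which.min(score)
    if (is.null(best) || score[i] < best$score) {
      best <- list(score = score[i], feature = j,
                   cut = (xs[cand[i]] + xs[cand[i] + 1]) / 2)
    }
  }
  best
}

# Grow one tree best-first. Returns a flat node table.
# leaf_value_fn(rows) computes the leaf prediction.
grow_tree <- function(X, y, w, max_leaves = 16L, min_leaf = 5L,
                      mtry = ncol(X), leaf_value_fn = NULL) {
  leaf_value_fn <- leaf_value_fn %||%
    function(rows) sum(w[rows] * y[rows]) / sum(w[rows])
  nodes <- list(list(rows = seq_len(nrow(X)), leaf = TRUE,
                     value = leaf_value_fn(seq_len(nrow(X))),
                     feature = NA_integer_, cut = NA_real_,
                     left = NA_integer_, right = NA_integer_))
  frontier <- 1L                                  # splittable leaf indices
  n_leaves <- 1L
  while (n_leaves < max_leaves && length(frontier)) {
    # pick the frontier node with the largest impurity decrease
    best_gain <- -Inf; best_node <- NA_integer_; best_split <- NULL
    drop <- integer()
    for (ni in frontier) {
      rows <- nodes[[ni]]$rows
      if (length(rows) < 2 * min_leaf) { drop <- c(drop, ni); next }
      feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
      sp <- .best_split(X, y, w, rows, feats, min_leaf)
      if (is.null(sp)) { drop <- c(drop, ni); next }
      sw <- sum(w[rows]); swy <- sum(w[rows] * y[rows])
      gain <- (-(swy^2 / sw)) - sp$score
      if (gain > best_gain) {
        best_gain <- gain; best_node <- ni; best_split <- sp
      }
    }
    frontier <- setdiff(frontier, drop)
    if (is.na(best_node) || best_gain <= 1e-12) break
    rows <- nodes[[best_node]]$rows
    go_left <- X[rows, best_split$feature] <= best_split$cut
    l_rows <- rows[go_left]; r_rows <- rows[!go_left]
    li <- length(nodes) + 1L; ri <- length(nodes) + 2L
    nodes[[li]] <- list(rows = l_rows, leaf = TRUE,
                        value = leaf_value_fn(l_rows),
                        feature = NA_integer_, cut = NA_real_,
                        left = NA_integer_, right = NA_integer_)
    nodes[[ri]] <- list(rows = r_rows, leaf = TRUE,
                        value = leaf_value_fn(r_rows),
                        feature = NA_integer_, cut = NA_real_,
                        left = NA_integer_, right = NA_integer_)
    nodes[[best_node]]$leaf <- FALSE
    nodes[[best_node]]$feature <- best_split$feature
    nodes[[best_node]]$cut <- best_split$cut
    nodes[[best_node]]$left <- li
    nodes[[best_node]]$right <- ri
    frontier <- c(setdiff(frontier, best_node), li, ri)
    n_leaves <- n_leaves + 1L
  }
  for (i in seq_along(nodes)) nodes[[i]]$rows <- NULL
  nodes
}

predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    ni <- 1L
    while (!nodes[[ni]]$leaf) {
      ni <- if (X[i, nodes[[ni]]$feature] <= nodes[[ni]]$cut) {
        nodes[[ni]]$left
      } else {
        nodes[[ni]]$right
      }
    }
    out[i] <- nodes[[ni]]$value
  }
  out
}

# Bagged classification forest: bootstrap rows, random feature subsets.
fit_forest <- function(X, y, w, n_trees = 200L, max_leaves = 16L,
                       min_leaf = 5L, mtry = max(1L, floor(sqrt(ncol(X))))) {
  trees <- vector("list", n_trees)
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- list(nodes = grow_tree(X[boot, , drop = FALSE], y[boot],
                                         w[boot], max_leaves, min_leaf, mtry))
  }
  structure(list(trees = trees), class = "pvl_forest")
}

predict_forest <- function(fit, X) {
  preds <- vapply(fit$trees, function(t) predict_tree(t$nodes, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

# Gradient boosting, bernoulli deviance, depth-limited trees with Newton
# leaf updates. interaction_depth d allows up to 2^d leaves.
fit_gbm <- function(X, y, w, n_trees = 100L, interaction_depth = 3L,
                    shrinkage = 0.05, bag_fraction = 0.8, min_leaf = 5L) {
  n <- nrow(X)
  p0 <- sum(w * y) / sum(w)
  f <- rep(log(p0 / (1 - p0)), n)
  init <- f[1]
  trees <- vector("list", n_trees)
  max_leaves <- as.integer(2^interaction_depth)
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    resid <- y - p                                # negative gradient
    bag <- sample.int(n, max(2L * min_leaf, floor(bag_fraction * n)))
    Xb <- X[bag, , drop = FALSE]
    nodes <- grow_tree(Xb, resid[bag], w[bag], max_leaves, min_leaf,
                       mtry = ncol(X))
    # Newton step per leaf: sum w*(y-p) / sum w*p*(1-p), computed on the bag
    leaf_of <- .leaf_index(nodes, Xb)
    for (li in unique(leaf_of)) {
      rows <- bag[leaf_of == li]
      num <- sum(w[rows] * resid[rows])
      den <- sum(w[rows] * p[rows] * (1 - p[rows]))
      nodes[[li]]$value <- if (den > 1e-12) num / den else 0
    }
    f <- f + shrinkage * predict_tree(nodes, X)
    trees[[t]] <- list(nodes = nodes)
  }
  structure(list(trees = trees, init = init, shrinkage = shrinkage),
            class = "pvl_gbm")
}

.leaf_index <- function(nodes, X) {
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    ni <- 1L
    while (!nodes[[ni]]$leaf) {
      ni <- if (X[i, nodes[[ni]]$feature] <= nodes[[ni]]$cut) {
        nodes[[ni]]$left
      } else {
        nodes[[ni]]$right
      }
    }
    out[i] <- ni
  }
  out
}

predict_gbm <- function(fit, X) {
  f <- rep(fit$init, nrow(X))
  for (t in fit$trees) f <- f + fit$shrinkage * predict_tree(t$nodes, X)
  1 / (1 + exp(-f))
}
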