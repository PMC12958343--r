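# CART-style regression trees, bagged forests, and gradient boosting.
# These back the tree families of the subset search and the SHAP ranking
# (no tree-ensemble package is available in the runtime environment).

# Grow a depth-limited variance-reduction regression tree. Nodes are rows of
# a table: feature (0 = leaf), threshold, left/right child ids, value
# (node mean), cover (sample count).
fit_tree <- function(X, y, max_depth = 3L, min_leaf = 2L) {
  X <- as.matrix(X)
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    node <- list(feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
                 value = mean(y[idx]), cover = length(idx))
    nodes[[id]] <<- node
    if (depth >= max_depth || length(idx) < 2L * min_leaf) return(id)
    best <- list(gain = 1e-12)
    sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
    parent_sse <- sse(y[idx])
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      ux <- sort(unique(xv))
      if (length(ux) < 2L) next
      cuts <- (head(ux, -1) + ux[-1]) / 2
      for (cut in cuts) {
        li <- idx[xv <= cut]
        ri <- idx[xv > cut]
        if (length(li) < min_leaf || length(ri) < min_leaf) next
        gain <- parent_sse - sse(y[li]) - sse(y[ri])
        if (gain > best$gain)
          best <- list(gain = gain, j = j, cut = cut, li = li, ri = ri)
      }
    }
    if (is.null(best$j)) return(id)
    lid <- grow(best$li, depth + 1L)
    rid <- grow(best$ri, depth + 1L)
    nodes[[id]]$feature <<- best$j
    nodes[[id]]$threshold <<- best$cut
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_along(y), 0L)
  structure(list(nodes = nodes, p = ncol(X)), class = "twofab_tree")
}

predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  apply(X, 1, function(x) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$feature == 0L) return(nd$value)
      id <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
    }
  })
}

tree_features <- function(tree) {
  f <- vapply(tree$nodes, function(nd) nd$feature, 0L)
  sort(unique(f[f > 0L]))
}

# Path-dependent conditional expectation E[tree(x) | x_S]: at a split on a
# feature in S follow x's branch; otherwise average children weighted by
# training cover.
tree_expect <- function(tree, x, S) {
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$feature == 0L) return(nd$value)
    if (nd$feature %in% S)
      return(walk(if (x[nd$feature] <= nd$threshold) nd$left else nd$right))
    wl <- tree$nodes[[nd$left]]$cover
    wr <- tree$nodes[[nd$right]]$cover
    (wl * walk(nd$left) + wr * walk(nd$right)) / (wl + wr)
  }
  walk(1L)
}

# Exact Shapley values of one tree for one sample: brute-force enumeration
# over the subsets of the tree's own used features (<= 2^depth - 1 of them),
# with the classic factorial weights. Features unused by the tree get 0.
tree_shapley <- function(tree, x) {
  U <- tree_features(tree)
  phi <- numeric(tree$p)
  u <- length(U)
  if (u == 0L) return(phi)
  v <- numeric(2^u)
  for (mask in 0:(2^u - 1L)) {
    S <- U[bitwAnd(mask, 2^(seq_len(u) - 1L)) > 0L]
    v[mask + 1L] <- tree_expect(tree, x, S)
  }
  fact <- factorial(0:u)
  for (k in seq_len(u)) {
    fk <- U[k]
    bit <- 2^(k - 1L)
    for (mask in 0:(2^u - 1L)) {
      if (bitwAnd(mask, bit) > 0L) next
      s <- sum(bitwAnd(mask, 2^(seq_len(u) - 1L)) > 0L)
      w <- fact[s + 1L] * fact[u - s] / fact[u + 1L]
      phi[fk] <- phi[fk] + w * (v[mask + bit + 1L] - v[mask + 1L])
    }
  }
  phi
}

# Gradient-boosted regression trees: squared loss, constant init at mean(y).
fit_gbt <- function(X, y, n_rounds = 200L, learning_rate = 0.1,
                    max_depth = 3L, min_leaf = 2L) {
  X <- as.matrix(X)
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    tr <- fit_tree(X, y - pred, max_depth, min_leaf)
    trees[[m]] <- tr
    pred <- pred + learning_rate * predict_tree(tr, X)
  }
  structure(list(trees = trees, f0 = f0, learning_rate = learning_rate,
                 p = ncol(X)), class = "twofab_gbt")
}

predict_gbt <- function(model, X) {
  X <- as.matrix(X)
  pred <- rep(model$f0, nrow(X))
  for (tr in model$trees) pred <- pred + model$learning_rate * predict_tree(tr, X)
  pred
}

# SHAP matrix (rows = samples, cols = features) plus per-sample base values.
# Additivity: base + rowSums(shap) == prediction, exactly up to float error.
gbt_shap <- function(model, X) {
  X <- as.matrix(X)
  phi <- matrix(0, nrow(X), model$p)
  base <- rep(model$f0, nrow(X))
  for (tr in model$trees) {
    b <- tree_expect(tr, rep(NA_real_, model$p), integer(0))
    base <- base + model$learning_rate * b
    for (i in seq_len(nrow(X)))
      phi[i, ] <- phi[i, ] + model$learning_rate * tree_shapley(tr, X[i, ])
  }
  list(shap = phi, base = base)
}

# Bagged random forest of regression trees with feature subsampling at the
# tree level (seeded; deterministic given the seed).
fit_forest <- function(X, y, n_trees = 100L, mtry = max(1L, ncol(X) %/% 3L),
                       max_depth = 6L, min_leaf = 2L, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  trees <- vector("list", n_trees)
  feats <- vector("list", n_trees)
  n <- nrow(X)
  for (m in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    fs <- sort(sample.int(ncol(X), min(mtry, ncol(X))))
    trees[[m]] <- fit_tree(X[idx, fs, drop = FALSE], y[idx], max_depth, min_leaf)
    feats[[m]] <- fs
  }
  structure(list(trees = trees, feats = feats, p = ncol(X)),
            class = "twofab_forest")
}

predict_forest <- function(model, X) {
  X <- as.matrix(X)
  acc <- numeric(nrow(X))
  for (m in seq_along(model$trees))
    acc <- acc + predict_tree(model$trees[[m]],
                              X[, model$feats[[m]], drop = FALSE])
  acc / length(model$trees)
}
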