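#' Pearson correlation matrix over features and labels
#'
#' Pairwise Pearson r over all numeric columns (descriptors plus `ln(v)` and
#' `Tm` if present). Constant columns have undefined correlations and are
#' reported as NA with a warning.
#'
#' @param table feature table (data.frame)
#' @return symmetric correlation matrix
#' @export
pearson_matrix <- function(table) {
  num <- table[vapply(table, is.numeric, TRUE)]
  if (nrow(num) < 3L) stop("need at least 3 rows for correlations")
  const <- vapply(num, function(v) stats::sd(v) == 0, TRUE)
  if (any(const))
    warning("constant columns have undefined correlations: ",
            paste(names(num)[const], collapse = ", "))
  suppressWarnings(stats::cor(as.matrix(num)))
}

#' SHAP ranking of features
#'
#' Fits a gradient-boosted tree regressor (depth 3, 200 rounds, learning rate
#' 0.1 — deterministic) to the labels and computes exact per-tree Shapley
#' attributions with path-dependent conditional expectations. Features are
#' ranked by mean absolute SHAP value. The additivity identity
#' `base + sum(shap) = prediction` holds for every row.
#'
#' @param table feature table containing the feature columns
#' @param label label column name (default "ln(v)") or a numeric vector
#' @param features feature column names (default [descriptor_codes()]
#'   intersected with the table)
#' @param n_rounds,max_depth,learning_rate boosting hyperparameters
#' @param drop features to exclude before ranking (the "drop-and-rerun"
#'   option, e.g. a low-ranked optional hotspot)
#' @return data.frame of class `shap_ranking`: feature, mean_abs_shap, rank;
#'   attributes `shap` (matrix), `base`, `prediction`
#' @export
shap_rank <- function(table, label = "ln(v)",
                      features = intersect(descriptor_codes(), names(table)),
                      n_rounds = 200L, max_depth = 3L, learning_rate = 0.1,
                      drop = NULL) {
  features <- setdiff(features, drop)
  X <- table[features]
  if (!all(vapply(X, is.numeric, TRUE))) stop("non-numeric feature columns")
  y <- if (is.character(label)) table[[label]] else label
  stopifnot(is.numeric(y), length(y) == nrow(X))
  model <- fit_gbt(as.matrix(X), y, n_rounds, learning_rate, max_depth)
  sh <- gbt_shap(model, as.matrix(X))
  mabs <- colMeans(abs(sh$shap))
  ord <- order(-mabs)
  out <- data.frame(feature = features[ord], mean_abs_shap = mabs[ord],
                    rank = seq_along(features), stringsAsFactors = FALSE)
  attr(out, "shap") <- sh$shap
  attr(out, "base") <- sh$base
  attr(out, "prediction") <- predict_gbt(model, as.matrix(X))
  class(out) <- c("shap_ranking", "data.frame")
  out
}

#' Enumerate all non-empty feature subsets
#'
#' All non-empty subsets of the given features, ordered by size then
#' lexicographically by member index; `k` features yield `2^k - 1` subsets
#' (9 -> 511).
#'
#' @param features character vector (or an integer count)
#' @return list of character (or integer) vectors
#' @export
enumerate_subsets <- function(features) {
  if (is.numeric(features) && length(features) == 1L)
    features <- seq_len(features)
  k <- length(features)
  stopifnot(k >= 1L)
  out <- list()
  for (size in seq_len(k))
    out <- c(out, utils::combn(features, size, simplify = FALSE))
  out
}

# --- model families ----------------------------------------------------------

# epsilon-SVR via the dual quadratic program (quadprog), kernels linear /
# poly(degree 3) / rbf with gamma = 1/p on standardized features.
svr_kernel <- function(X, Z, kernel, gamma, coef0 = 0, degree = 3) {
  G <- X %*% t(Z)
  switch(kernel,
         linear = G,
         poly = (gamma * G + coef0)^degree,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
           exp(-gamma * pmax(d2, 0))
         },
         stop("unknown kernel: ", kernel))
}

fit_svr <- function(X, y, C = 1, epsilon = 0.1, kernel = "rbf",
                    gamma = 1 / ncol(X)) {
  X <- as.matrix(X); n <- nrow(X)
  K <- svr_kernel(X, X, kernel, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K))
  diag(D) <- diag(D) + 1e-8 * max(1, mean(diag(K)))
  d <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  alpha <- sol$solution[seq_len(n)] - sol$solution[n + seq_len(n)]
  f0 <- as.numeric(K %*% alpha)
  tol <- 1e-6 * C
  up <- sol$solution[seq_len(n)]
  dn <- sol$solution[n + seq_len(n)]
  bcand <- c((y - epsilon - f0)[up > tol & up < C - tol],
             (y + epsilon - f0)[dn > tol & dn < C - tol])
  b <- if (length(bcand)) mean(bcand) else stats::median(y - f0)
  structure(list(X = X, alpha = alpha, b = b, kernel = kernel, gamma = gamma),
            class = "twofab_svr")
}

predict_svr <- function(model, X) {
  K <- svr_kernel(as.matrix(X), model$X, model$kernel, model$gamma)
  as.numeric(K %*% model$alpha + model$b)
}

# PLS1 regression via NIPALS on centred data.
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  p <- ncol(X); A <- min(ncomp, p, nrow(X) - 1L)
  W <- P <- matrix(0, p, A); q <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    pv <- drop(crossprod(E, t_)) / tt
    qa <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pv)
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  if (A == 0L) return(structure(list(beta = rep(0, p), xm = xm, ym = ym),
                                class = "twofab_pls"))
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(beta = drop(beta), xm = xm, ym = ym), class = "twofab_pls")
}

predict_pls <- function(model, X) {
  drop(sweep(as.matrix(X), 2, model$xm) %*% model$beta) + model$ym
}

fit_mlr <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  structure(list(coef = qr.coef(qr(X1), y)), class = "twofab_mlr")
}

predict_mlr <- function(model, X) {
  cf <- model$coef
  cf[is.na(cf)] <- 0
  drop(cbind(1, as.matrix(X)) %*% cf)
}

# hyperparameter grids per family
family_grid <- function(family, p) {
  switch(family,
         mlr = data.frame(dummy = 1),
         pls = data.frame(ncomp = seq_len(min(p, 10L))),
         svr = expand.grid(C = c(0.1, 1, 10, 100),
                           epsilon = c(0.01, 0.1, 0.2),
                           kernel = c("linear", "poly", "rbf"),
                           stringsAsFactors = FALSE),
         tree = data.frame(max_depth = c(2L, 3L, 5L)),
         rf = data.frame(mtry = unique(c(max(1L, p %/% 3L), p))),
         stop("unknown family: ", family))
}

fit_family <- function(family, X, y, par, seed = 1L) {
  switch(family,
         mlr = fit_mlr(X, y),
         pls = fit_pls(X, y, par$ncomp),
         svr = fit_svr(X, y, C = par$C, epsilon = par$epsilon,
                       kernel = par$kernel),
         tree = fit_tree(X, y, max_depth = par$max_depth),
         rf = fit_forest(X, y, n_trees = 100L, mtry = par$mtry, seed = seed))
}

predict_family <- function(family, model, X) {
  switch(family,
         mlr = predict_mlr(model, X),
         pls = predict_pls(model, X),
         svr = predict_svr(model, X),
         tree = predict_tree(model, X),
         rf = predict_forest(model, X))
}

#' Cross-validation fold assignment
#'
#' Deterministic given (n, k, seed): the folds depend on nothing else, so
#' reruns are bitwise reproducible for deterministic model families.
#'
#' @param n number of rows
#' @param k number of folds (default 5)
#' @param seed RNG seed
#' @return integer fold labels of length n
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# leakage-free per-fold standardization + CV. Returns mean per-fold R^2 and
# out-of-fold predictions.
cv_model <- function(family, X, y, par, folds, standardize = TRUE, seed = 1L) {
  k <- max(folds)
  oof <- rep(NA_real_, length(y))
  r2 <- numeric(k)
  for (fold in seq_len(k)) {
    te <- folds == fold; tr <- !te
    Xtr <- as.matrix(X[tr, , drop = FALSE]); Xte <- as.matrix(X[te, , drop = FALSE])
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd); sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    if (stats::sd(y[tr]) == 0) stop("degenerate fold: constant training labels")
    m <- fit_family(family, Xtr, y[tr], par, seed = seed + fold)
    pr <- predict_family(family, m, Xte)
    oof[te] <- pr
    sst <- sum((y[te] - mean(y[te]))^2)
    r2[fold] <- 1 - sum((y[te] - pr)^2) / sst
  }
  list(mean_r2 = mean(r2), oof = oof)
}

#' Exhaustive subset search over SHAP-ranked features
#'
#' Ranks features by mean |SHAP|, keeps the top `top_k` (default 9, yielding
#' 511 subsets), and for every non-empty subset runs a cross-validated grid
#' search over the requested model families (5-fold, scored by mean per-fold
#' R^2, features standardised on the training folds only). Reports the best
#' model per subset, the global best, and parity pairs from the global best's
#' out-of-fold predictions (plus its refit-on-all in-sample predictions,
#' since printed parity conventions differ between studies).
#'
#' @param table feature table with label column
#' @param label label column name (default "ln(v)")
#' @param features candidate feature columns (default descriptors present)
#' @param top_k number of top-ranked features to search over (default 9)
#' @param families model families (subset of mlr, pls, svr, tree, rf)
#' @param folds number of CV folds (default 5)
#' @param seed seed for fold assignment and stochastic families
#' @param drop features to exclude before ranking
#' @param ranking optional precomputed [shap_rank()] result (skips refitting)
#' @return list of class `model_report`: `ranking`, `top_features`, `results`
#'   (per subset x family best), `best` (family, params, subset, cv_r2),
#'   `parity` (actual, predicted_oof, predicted_insample), `pearson`
#' @export
subset_search <- function(table, label = "ln(v)",
                          features = intersect(descriptor_codes(), names(table)),
                          top_k = 9L, families = c("mlr", "pls", "svr"),
                          folds = 5L, seed = 1L, drop = NULL, ranking = NULL) {
  if (is.null(ranking))
    ranking <- shap_rank(table, label, features, drop = drop)
  top_k <- min(top_k, nrow(ranking))
  top <- ranking$feature[seq_len(top_k)]
  y <- table[[label]]
  fold_id <- make_folds(length(y), folds, seed)
  subsets <- enumerate_subsets(top)
  res <- vector("list", length(subsets) * length(families))
  ri <- 0L
  best <- list(cv_r2 = -Inf)
  for (si in seq_along(subsets)) {
    sub <- subsets[[si]]
    X <- table[sub]
    for (fam in families) {
      grid <- family_grid(fam, length(sub))
      fam_best <- list(cv_r2 = -Inf)
      for (gi in seq_len(nrow(grid))) {
        par <- grid[gi, , drop = FALSE]
        cv <- cv_model(fam, X, y, par, fold_id, seed = seed)
        if (cv$mean_r2 > fam_best$cv_r2)
          fam_best <- list(cv_r2 = cv$mean_r2, par = par, oof = cv$oof)
      }
      ri <- ri + 1L
      res[[ri]] <- data.frame(subset = paste(sub, collapse = " + "),
                              size = length(sub), family = fam,
                              params = paste(names(fam_best$par),
                                             unlist(fam_best$par),
                                             sep = "=", collapse = ", "),
                              cv_r2 = fam_best$cv_r2,
                              stringsAsFactors = FALSE)
      if (fam_best$cv_r2 > best$cv_r2)
        best <- list(cv_r2 = fam_best$cv_r2, family = fam,
                     params = fam_best$par, subset = sub, oof = fam_best$oof)
    }
  }
  results <- do.call(rbind, res[seq_len(ri)])
  # refit global best on all rows for the in-sample parity variant
  Xb <- as.matrix(table[best$subset])
  mu <- colMeans(Xb); sdv <- apply(Xb, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(Xb, 2, mu), 2, sdv, "/")
  refit <- fit_family(best$family, Xs, y, best$params, seed = seed)
  parity <- data.frame(actual = y, predicted_oof = best$oof,
                       predicted_insample = predict_family(best$family, refit, Xs))
  structure(list(ranking = ranking, top_features = top, results = results,
                 best = best[c("family", "params", "subset", "cv_r2")],
                 parity = parity, pearson = pearson_matrix(table),
                 n_subsets = length(subsets), seed = seed),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Model report: ", x$n_subsets, " subsets of top ",
      length(x$top_features), " SHAP-ranked features\n", sep = "")
  cat("Best: ", x$best$family, " [",
      paste(names(x$best$params), unlist(x$best$params), sep = "=",
            collapse = ", "),
      "] on {", paste(x$best$subset, collapse = ", "), "}\n", sep = "")
  cat("Cross-validated R^2 = ", round(x$best$cv_r2, 4), "\n", sep = "")
  invisible(x)
}
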