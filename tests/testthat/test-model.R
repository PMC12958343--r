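test_that("Pearson matrix reproduces exact linear relations and flags constants", {
  x <- 1:20
  tab <- data.frame(x = x, y = 2 * x + 1, z = -x, w = rep(3, 20))
  expect_warning(r <- pearson_matrix(tab), "constant")
  expect_equal(r["x", "y"], 1)
  expect_equal(r["x", "z"], -1)
  expect_equal(unname(diag(r)[1:3]), rep(1, 3))
  expect_true(all(is.na(r["w", c("x", "y", "z")])))
  expect_true(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  expect_error(pearson_matrix(tab[1:2, ]), "3 rows")
})

test_that("SHAP attributions satisfy additivity and rank a dominant feature first", {
  tab <- model_table()
  rk <- shap_rank(tab, n_rounds = 80L)
  sh <- attr(rk, "shap")
  expect_equal(attr(rk, "base") + rowSums(sh), attr(rk, "prediction"),
               tolerance = 1e-6)
  # the four planted features occupy the top four ranks
  expect_setequal(rk$feature[1:4],
                  c("r_288-290", "r_126-128", "Last 80 ns mean RMSD",
                    "r_31-36"))

  # noise-free dominant feature ranks first in >= 95% of seeded repeats
  feats <- descriptor_codes()[1:8]
  wins <- 0L
  for (s in 1:20) {
    t2 <- generate_feature_table(synth_feature_config(
      seed = 100 + s, noise_sd = 0.01, informative = c("r_47-51" = 2)))
    r2 <- shap_rank(t2, features = feats, n_rounds = 50L)
    wins <- wins + (r2$feature[1] == "r_47-51")
  }
  expect_gte(wins / 20, 0.95)
})

test_that("SHAP attribution spreads out when the label is independent of features", {
  feats <- descriptor_codes()[1:8]
  acc <- setNames(numeric(length(feats)), feats)
  for (s in 1:10) {
    t2 <- generate_feature_table(synth_feature_config(seed = 200 + s,
                                                      informative = c()))
    set.seed(300 + s)
    t2[["ln(v)"]] <- rnorm(nrow(t2))
    r2 <- shap_rank(t2, features = feats, n_rounds = 50L)
    acc[r2$feature] <- acc[r2$feature] + r2$mean_abs_shap
  }
  expect_lt(max(acc), 3 * min(acc))
})

test_that("subset enumeration is complete and deterministically ordered", {
  expect_length(enumerate_subsets(9), 511L)
  expect_length(enumerate_subsets(1), 1L)
  s3 <- enumerate_subsets(c("a", "b", "c"))
  expect_length(s3, 7L)
  expect_identical(s3[[1]], "a")
  expect_identical(s3[[4]], c("a", "b"))
  expect_identical(s3[[7]], c("a", "b", "c"))
  sizes <- lengths(enumerate_subsets(5))
  expect_true(all(diff(sizes) >= 0))
})

test_that("model families fit their canonical cases", {
  set.seed(31)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] - X[, 2] + 0.5
  # MLR exact on linear data
  m <- twofab:::fit_mlr(X, y)
  expect_equal(twofab:::predict_mlr(m, X), y, tolerance = 1e-10)
  # PLS with full components equals MLR on full-rank data
  p <- twofab:::fit_pls(X, y, ncomp = 3)
  expect_equal(twofab:::predict_pls(p, X), y, tolerance = 1e-8)
  # SVR (linear kernel, generous C, small epsilon) tracks a linear function
  s <- twofab:::fit_svr(X, y, C = 100, epsilon = 0.01, kernel = "linear")
  expect_lt(max(abs(twofab:::predict_svr(s, X) - y)), 0.05)
  # SVR rbf interpolates a smooth nonlinear function on its training points
  y2 <- sin(X[, 1])
  s2 <- twofab:::fit_svr(X, y2, C = 100, epsilon = 0.01, kernel = "rbf")
  expect_gt(cor(twofab:::predict_svr(s2, X), y2)^2, 0.95)
  # regression tree learns an axis-aligned step exactly
  ystep <- ifelse(X[, 2] > 0, 5, -5)
  tr <- twofab:::fit_tree(X, ystep, max_depth = 2)
  expect_equal(twofab:::predict_tree(tr, X), ystep)
  # forest is deterministic given a seed
  f1 <- twofab:::fit_forest(X, y, n_trees = 20, seed = 5)
  f2 <- twofab:::fit_forest(X, y, n_trees = 20, seed = 5)
  expect_identical(twofab:::predict_forest(f1, X),
                   twofab:::predict_forest(f2, X))
})

test_that("fold assignment is reproducible and standardization never leaks", {
  expect_identical(make_folds(49, 5, seed = 2), make_folds(49, 5, seed = 2))
  expect_false(identical(make_folds(49, 5, 2), make_folds(49, 5, 3)))
  expect_error(make_folds(3, 5), "n >= k")

  # sentinel outlier: test-fold statistics must not enter the training-fold
  # scaling, so when one fold-1 row becomes a wild outlier the predictions
  # for the other fold-1 rows (scaled with training statistics only) are
  # unchanged. A leaky scaler would rescale the whole held-out fold.
  set.seed(33)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  y <- X[, 1] + rnorm(n, sd = 0.1)
  folds <- make_folds(n, 5, seed = 1)
  base <- twofab:::cv_model("pls", X, y, data.frame(ncomp = 2), folds)
  Xout <- X
  sentinel <- which(folds == 1)[1]
  Xout[sentinel, ] <- c(1e6, -1e6)
  pert <- twofab:::cv_model("pls", Xout, y, data.frame(ncomp = 2), folds)
  clean <- folds == 1 & seq_len(n) != sentinel
  expect_equal(pert$oof[clean], base$oof[clean], tolerance = 1e-10)
})

test_that("subset search recovers a planted linear law and its features", {
  tab <- model_table()
  rep1 <- subset_search(tab, families = "mlr", seed = 1)
  expect_equal(rep1$n_subsets, 511L)
  expect_gte(rep1$best$cv_r2, 0.9)
  expect_true(all(c("r_288-290", "r_126-128", "Last 80 ns mean RMSD",
                    "r_31-36") %in% rep1$best$subset))
  expect_equal(rep1$best$cv_r2, max(rep1$results$cv_r2))
  expect_equal(nrow(rep1$parity), 49L)
  expect_gt(cor(rep1$parity$actual, rep1$parity$predicted_oof)^2, 0.85)
  # single feature, y = x: MLR is exact
  toy <- data.frame(x = 1:20, y = as.numeric(1:20), check.names = FALSE)
  names(toy) <- c("x", "ln(v)")
  r <- subset_search(toy, features = "x", top_k = 1, families = "mlr",
                     ranking = data.frame(feature = "x", mean_abs_shap = 1,
                                          rank = 1))
  expect_equal(r$best$cv_r2, 1, tolerance = 1e-6)
})

test_that("best subset-search score never decreases when top_k grows (MLR)", {
  tab <- model_table()
  rk <- shap_rank(tab, n_rounds = 80L)
  r3 <- subset_search(tab, families = "mlr", seed = 7, top_k = 3, ranking = rk)
  r5 <- subset_search(tab, families = "mlr", seed = 7, top_k = 5, ranking = rk)
  expect_gte(r5$best$cv_r2, r3$best$cv_r2 - 1e-12)
})

test_that("shuffled labels yield no predictive power (negative control)", {
  tab <- model_table()
  rk <- shap_rank(tab, n_rounds = 60L)
  scores <- vapply(1:10, function(s) {
    t2 <- tab
    set.seed(400 + s)
    t2[["ln(v)"]] <- sample(t2[["ln(v)"]])
    subset_search(t2, families = "mlr", seed = s, ranking = rk)$best$cv_r2
  }, 0)
  expect_lte(median(scores), 0.2)
})
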