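test_that("fit_regressor handles determinism, importances, and degenerate targets", {
  set.seed(5)
  X <- noise_matrix(40, 6)
  y <- 2 * X[, 3] + rnorm(40, sd = 0.1)
  f1 <- fit_regressor(X, y, model_spec("gbtree", seed = 2))
  f2 <- fit_regressor(X, y, model_spec("gbtree", seed = 2))
  expect_identical(predict(f1, X), predict(f2, X))
  imp <- raw_importance(f1)
  expect_equal(names(which.max(imp)), colnames(X)[3])

  rf <- fit_regressor(X, y, model_spec("random_forest", seed = 2))
  expect_equal(names(which.max(raw_importance(rf))), colnames(X)[3])
  expect_identical(predict(rf, X),
                   predict(fit_regressor(X, y, model_spec("random_forest",
                                                          seed = 2)), X))

  expect_warning(fc <- fit_regressor(X, rep(3, 40)), "degenerate")
  expect_equal(predict(fc, X), rep(3, 40))
  expect_error(predict(f1, X[, -2]), "missing signature gene")
})

test_that("Boruta confirms a copy of the target and partitions all candidates", {
  set.seed(8)
  n <- 50
  y <- rnorm(n)
  X <- cbind(COPY = y, noise_matrix(n, 9))
  dec <- boruta_select(X, y, max_iter = 30,
                       spec = model_spec("random_forest", n_trees = 200,
                                         seed = 1))
  expect_true("COPY" %in% dec$confirmed)
  expect_equal(sort(c(dec$confirmed, dec$rejected, dec$tentative)),
               sort(colnames(X)))
  expect_true(all(dec$decisions$verdict %in%
                  c("confirmed", "rejected", "tentative")))
  expect_error(boruta_select(X, y, max_iter = 3), "underpowered")
})

test_that("Boruta separates planted from noise features on a small study", {
  res <- vapply(1:5, function(s) {
    set.seed(300 + s)
    n <- 60
    X <- noise_matrix(n, 30, "F")
    planted <- paste0("F", sprintf("%03d", 1:3))
    y <- X[, 1] + X[, 2] + X[, 3] + rnorm(n, sd = 0.4)
    dec <- boruta_select(X, y, max_iter = 40,
                         spec = model_spec("random_forest", n_trees = 200,
                                           seed = s))
    c(planted_in = mean(planted %in% dec$confirmed),
      noise_rejected = mean(setdiff(colnames(X), planted) %in% dec$rejected))
  }, numeric(2))
  expect_gte(sum(res["planted_in", ] == 1), 4)
  expect_gt(mean(res["noise_rejected", ]), 0.8)
})

test_that("holdout split is stratified, sized, and deterministic", {
  strata <- rep(c("a", "b", "c", "d"), each = 13)
  h1 <- drugsig:::holdout_split(52, 11, strata, seed = 4)
  h2 <- drugsig:::holdout_split(52, 11, strata, seed = 4)
  expect_identical(h1, h2)
  expect_length(h1, 11)
  # proportional allocation: 11/4 per 13-sample stratum, so 2 or 3 each
  tab <- table(strata[h1])
  expect_true(all(tab %in% 2:3))
  expect_length(drugsig:::holdout_split(52, 11, NULL, seed = 1), 11)
})

test_that("repeated-CV folds partition every sample with balanced sizes", {
  n <- 41; folds <- 10
  with_seed <- drugsig:::with_seed
  with_seed(99, {
    for (rep in 1:3) {
      fold <- sample(rep(seq_len(folds), length.out = n))
      expect_length(fold, n)
      expect_true(all(diff(range(table(fold))) <= 1))
    }
  })
  # cv_rmse of a perfect predictor's target is small and reproducible
  set.seed(12)
  X <- noise_matrix(41, 3)
  y <- X[, 1]
  a <- drugsig:::cv_rmse(X, y, model_spec("gbtree", n_trees = 50,
                                          max_depth = 1), 2, 10, seed = 5)
  b <- drugsig:::cv_rmse(X, y, model_spec("gbtree", n_trees = 50,
                                          max_depth = 1), 2, 10, seed = 5)
  expect_identical(a, b)
  expect_lt(a, sd(y))
})

test_that("backward elimination produces a complete, self-consistent trace", {
  set.seed(17)
  n <- 52
  X <- cbind(CAUSAL = rnorm(n), noise_matrix(n, 2))
  y <- 6.5 + 1.5 * X[, "CAUSAL"] + rnorm(n, sd = 0.15)
  rank_order <- c("CAUSAL", colnames(X)[2:3])
  res <- backward_eliminate(X, y, rank_order,
                            tune_grid = data.frame(max_depth = 1L,
                                                   n_trees = 150L, eta = 0.1),
                            cv_repeats = 2L, cv_folds = 5L,
                            holdout_size = 11L, seed = 6)
  tr <- res$trace
  # one step per size, down to a single gene
  expect_equal(nrow(tr), 3)
  expect_equal(tr$n_genes, c(3, 2, 1))
  for (i in 2:nrow(tr)) {
    prev <- strsplit(tr$genes[i - 1], ",")[[1]]
    cur <- strsplit(tr$genes[i], ",")[[1]]
    expect_length(setdiff(prev, cur), 1)
    expect_equal(setdiff(prev, cur), tr$removed_gene[i])
  }
  # the chosen set is the criterion argmax (ties to the smaller set)
  best <- order(-tr$criterion, tr$n_genes)[1]
  expect_equal(res$best_step, tr$step[best])
  expect_setequal(res$signature, strsplit(tr$genes[best], ",")[[1]])
  expect_true("CAUSAL" %in% res$signature)
  expect_true(all(tr$criterion >= 0 & tr$criterion <= 2))
  # holdout never enters the internal-train partition
  expect_length(intersect(res$holdout_idx,
                          setdiff(seq_len(n), res$holdout_idx)), 0)

  # self-consistency: re-evaluating the winning step reproduces its row
  hold <- res$holdout_idx
  intern <- setdiff(seq_len(n), hold)
  redo <- drugsig:::eval_gene_set(X, y, res$signature, intern, hold,
                                  data.frame(max_depth = 1L, n_trees = 150L,
                                             eta = 0.1),
                                  2L, 5L, "holdout", seed = 6,
                                  step = res$best_step)
  expect_equal(redo$twofold, tr$twofold[best])
  expect_equal(redo$fourfold, tr$fourfold[best])
  expect_equal(redo$cv_rmse, tr$cv_rmse[best])
})

test_that("variable importance is normalized, ordered, and exact for one gene", {
  set.seed(23)
  ds <- generate_dataset(small_config(seed = 23))
  fit <- suppressMessages(suppressWarnings(
    derive_signature(ds$expression, ds$sensitivity,
                     control = sig_control(cv_repeats = 2, cv_folds = 5,
                                           boruta_trees = 200),
                     seed = 23)))
  vi <- variable_importance(fit)
  expect_equal(sum(vi$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(vi$importance) <= 1e-12))
  expect_setequal(vi$gene, fit$signature)
  if (length(fit$signature) == 1L) expect_equal(vi$importance, 1)
  expect_error(variable_importance(list()), "fitted")
})
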