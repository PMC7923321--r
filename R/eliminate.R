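#' Repeated k-fold cross-validated RMSE of a boosted-tree config
#'
#' Out-of-fold RMSE averaged over `repeats` independent fold assignments.
#' Every sample appears in exactly one fold per repeat; fold sizes differ by
#' at most one.
#'
#' @param X samples x genes matrix.
#' @param y target.
#' @param spec a [model_spec()].
#' @param repeats,folds CV layout (default 5 x 10).
#' @param seed seed for the fold assignments.
#' @return mean out-of-fold RMSE.
#' @keywords internal
cv_rmse <- function(X, y, spec, repeats = 5L, folds = 10L, seed = 1L) {
  n <- nrow(X)
  stopifnot(n >= folds)
  with_seed(seed, {
    reps <- vapply(seq_len(repeats), function(r) {
      fold <- sample(rep(seq_len(folds), length.out = n))
      oof <- numeric(n)
      for (f in seq_len(folds)) {
        hold <- fold == f
        fit <- fit_regressor(X[!hold, , drop = FALSE], y[!hold], spec)
        oof[hold] <- predict(fit, X[hold, , drop = FALSE])
      }
      rmse(oof, y)
    }, 0)
    mean(reps)
  })
}

#' Single stratified train/holdout split
#'
#' Samples the holdout within tumor-type strata (proportional allocation,
#' largest-remainder rounding) when labels are given.
#'
#' @param n cohort size.
#' @param holdout_size holdout count.
#' @param strata optional per-sample labels.
#' @param seed seed.
#' @return integer indices of the holdout samples.
#' @keywords internal
holdout_split <- function(n, holdout_size, strata = NULL, seed = 1L) {
  stopifnot(holdout_size >= 1, holdout_size < n)
  with_seed(seed, {
    if (is.null(strata)) return(sort(sample.int(n, holdout_size)))
    idx_by <- split(seq_len(n), strata)
    quota <- holdout_size * lengths(idx_by) / n
    take <- floor(quota)
    rem <- holdout_size - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    take <- pmin(take, lengths(idx_by))
    short <- holdout_size - sum(take)
    if (short > 0) {  # strata exhausted; top up from the largest remainder
      room <- lengths(idx_by) - take
      for (i in order(room, decreasing = TRUE)) {
        add <- min(short, room[i]); take[i] <- take[i] + add; short <- short - add
        if (short == 0) break
      }
    }
    sort(unlist(Map(function(ix, k) if (k > 0) sample(ix, k) else integer(),
                    idx_by, take), use.names = FALSE))
  })
}

#' One-by-one backward elimination under the fold-accuracy criterion
#'
#' Splits the cohort once into an internal-train and holdout partition
#' (41/11-style sizes, stratified by tumor type when given). Starting from
#' all candidate genes, the lowest-ranked remaining gene is removed at each
#' step; at every step the boosted-tree depth is tuned by repeated k-fold
#' CV RMSE on the internal-train partition, the tuned model is refit on the
#' internal-train partition and scored on the holdout with two-fold and
#' four-fold accuracy. The signature returned is the gene set maximizing
#' criterion = twofold + fourfold (tie: the smaller set).
#'
#' @param X samples x candidate-genes matrix.
#' @param y \eqn{-\log_{10}}(M) target.
#' @param rank_order character vector ranking the candidates best-first
#'   (e.g. the RReliefF order); genes leave worst-first.
#' @param tune_grid data.frame of candidate hyperparameters with columns
#'   `max_depth`, `n_trees`, `eta`; the default grid spans depth-1
#'   (additive) boosting at several learning rates plus a depth-2 option
#'   for interactions.
#' @param cv_repeats,cv_folds CV layout for tuning (default 5 x 10).
#' @param holdout_size holdout partition size (default 11).
#' @param strata optional tumor-type labels for the stratified split.
#' @param criterion_on `"holdout"` (default) scores the accuracy criterion
#'   on the holdout partition; `"cv"` scores it on the CV out-of-fold
#'   predictions of the internal-train partition.
#' @param seed master seed for split, CV and fits.
#' @return list of class `elimination_result`: `trace` (data.frame with
#'   step, n_genes, removed_gene, genes, max_depth, cv_rmse, twofold,
#'   fourfold, criterion), `signature`, `best_step`, `holdout_idx`,
#'   `best_spec`.
#' @export
backward_eliminate <- function(X, y, rank_order,
                               tune_grid = data.frame(max_depth = c(1L, 1L,
                                                                    1L, 2L),
                                                      n_trees = c(100L, 300L,
                                                                  300L, 300L),
                                                      eta = c(0.3, 0.1, 0.05,
                                                              0.1)),
                               cv_repeats = 5L, cv_folds = 10L,
                               holdout_size = 11L, strata = NULL,
                               criterion_on = c("holdout", "cv"),
                               seed = 1L) {
  criterion_on <- match.arg(criterion_on)
  if (!is.matrix(X)) X <- as.matrix(X)
  genes <- colnames(X)
  stopifnot(length(genes) >= 2, all(genes %in% rank_order))
  if (holdout_size < 1 || holdout_size >= nrow(X))
    stop("holdout size must be in [1, n-1]")
  hold <- holdout_split(nrow(X), holdout_size, strata, seed)
  tr <- setdiff(seq_len(nrow(X)), hold)
  if (length(tr) < cv_folds)
    stop("internal-train partition smaller than the number of CV folds")

  order_worst_first <- rev(rank_order[rank_order %in% genes])
  current <- genes
  steps <- list()
  removed <- NA_character_
  for (step in seq_along(genes)) {
    res <- eval_gene_set(X, y, current, tr, hold, tune_grid,
                         cv_repeats, cv_folds, criterion_on, seed, step)
    steps[[step]] <- data.frame(step = step, n_genes = length(current),
                                removed_gene = removed,
                                genes = paste(current, collapse = ","),
                                max_depth = res$spec$max_depth,
                                n_trees = res$spec$n_trees, eta = res$spec$eta,
                                cv_rmse = res$cv_rmse, twofold = res$twofold,
                                fourfold = res$fourfold,
                                criterion = res$twofold + res$fourfold,
                                stringsAsFactors = FALSE)
    if (length(current) == 1L) break
    removed <- order_worst_first[step]
    current <- setdiff(current, removed)
  }
  trace <- do.call(rbind, steps)
  # argmax of the criterion; ties resolved toward the smaller gene set
  best <- order(-trace$criterion, trace$n_genes)[1]
  signature <- strsplit(trace$genes[best], ",", fixed = TRUE)[[1]]
  best_spec <- model_spec("gbtree", n_trees = trace$n_trees[best],
                          max_depth = trace$max_depth[best],
                          eta = trace$eta[best], seed = seed)
  structure(list(trace = trace, signature = signature,
                 best_step = trace$step[best], holdout_idx = hold,
                 best_spec = best_spec),
            class = "elimination_result")
}

# tune depth by CV on the internal-train partition, refit, score holdout
eval_gene_set <- function(X, y, current, tr, hold, tune_grid, cv_repeats,
                          cv_folds, criterion_on, seed, step) {
  Xtr <- X[tr, current, drop = FALSE]
  cvs <- vapply(seq_len(nrow(tune_grid)), function(g) {
    spec <- model_spec("gbtree", n_trees = tune_grid$n_trees[g],
                       max_depth = tune_grid$max_depth[g],
                       eta = tune_grid$eta[g], seed = seed)
    cv_rmse(Xtr, y[tr], spec, cv_repeats, cv_folds, seed = seed + step)
  }, 0)
  g <- which.min(cvs)
  spec <- model_spec("gbtree", n_trees = tune_grid$n_trees[g],
                     max_depth = tune_grid$max_depth[g], eta = tune_grid$eta[g],
                     seed = seed)
  fit <- fit_regressor(Xtr, y[tr], spec)
  if (criterion_on == "holdout") {
    pred <- predict(fit, X[hold, current, drop = FALSE])
    obs <- y[hold]
  } else {
    pred <- with_seed(seed + step, {
      fold <- sample(rep(seq_len(cv_folds), length.out = length(tr)))
      oof <- numeric(length(tr))
      for (f in seq_len(cv_folds)) {
        h <- fold == f
        m <- fit_regressor(Xtr[!h, , drop = FALSE], y[tr][!h], spec)
        oof[h] <- predict(m, Xtr[h, , drop = FALSE])
      }
      oof
    })
    obs <- y[tr]
  }
  list(spec = spec, cv_rmse = cvs[g],
       twofold = fold_accuracy(10^(-pred), 10^(-obs), 2),
       fourfold = fold_accuracy(10^(-pred), 10^(-obs), 4))
}
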