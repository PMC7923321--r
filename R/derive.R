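#' Control parameters for signature derivation
#'
#' Collects every tunable of the derivation funnel with the pipeline's
#' standard defaults: correlation screen at p <= 0.05, optional biological
#' filters, RReliefF top-100 hand-off, Boruta at alpha 0.05, backward
#' elimination with 5x10-fold CV tuning and an 11-sample holdout scored by
#' the two-fold + four-fold accuracy sum.
#'
#' @param alpha_corr correlation-screen significance level.
#' @param combine_filters how pathway- and network-filter outputs combine
#'   when both are supplied: `"union"` (default, permissive) or
#'   `"intersection"`.
#' @param relief_k RReliefF neighbor count.
#' @param top_n_relief genes passed from the Relief ranking to Boruta.
#' @param alpha_boruta Boruta binomial-test level (Bonferroni-corrected).
#' @param boruta_max_iter maximum Boruta iterations.
#' @param boruta_trees random-forest size inside Boruta.
#' @param cv_repeats,cv_folds repeated-CV layout for hyperparameter tuning.
#' @param holdout_size samples held out for the accuracy criterion; the
#'   default 11 reproduces a 41/11 split on a 52-sample cohort. Cohorts of
#'   other sizes use `round(n * 11 / 52)` (at least 1) unless set
#'   explicitly.
#' @param criterion_on `"holdout"` or `"cv"`; see [backward_eliminate()].
#' @param tune_grid hyperparameter grid; see [backward_eliminate()].
#' @param exclude_lineage lineage removed before training (default
#'   `"blood"`); `NULL` to keep all samples.
#' @return a list of class `sig_control`.
#' @export
sig_control <- function(alpha_corr = 0.05,
                        combine_filters = c("union", "intersection"),
                        relief_k = 10L, top_n_relief = 100L,
                        alpha_boruta = 0.05, boruta_max_iter = 50L,
                        boruta_trees = 300L,
                        cv_repeats = 5L, cv_folds = 10L,
                        holdout_size = NULL,
                        criterion_on = c("holdout", "cv"),
                        tune_grid = data.frame(max_depth = c(1L, 1L, 1L, 2L),
                                               n_trees = c(100L, 300L, 300L,
                                                           300L),
                                               eta = c(0.3, 0.1, 0.05, 0.1)),
                        exclude_lineage = "blood") {
  structure(list(alpha_corr = alpha_corr,
                 combine_filters = match.arg(combine_filters),
                 relief_k = as.integer(relief_k),
                 top_n_relief = as.integer(top_n_relief),
                 alpha_boruta = alpha_boruta,
                 boruta_max_iter = as.integer(boruta_max_iter),
                 boruta_trees = as.integer(boruta_trees),
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds),
                 holdout_size = holdout_size,
                 criterion_on = match.arg(criterion_on),
                 tune_grid = tune_grid,
                 exclude_lineage = exclude_lineage),
            class = "sig_control")
}

#' Derive a drug-sensitivity gene signature
#'
#' Runs the full derivation funnel on an expression matrix and an IC50
#' table: sample alignment and lineage exclusion, Pearson correlation
#' screen, optional pathway/network filters, RReliefF ranking (top 100),
#' Boruta shadow-feature confirmation, and one-by-one backward elimination
#' of the confirmed genes under a gradient-boosted-tree regressor, keeping
#' the gene set with the highest two-fold + four-fold holdout accuracy sum.
#' The final model is refit on the full training cohort with the
#' CV-selected hyperparameters of the winning step.
#'
#' @param expression an `expr_matrix` (genes x samples, log2).
#' @param sensitivity a `sens_table` with Molar IC50s.
#' @param gene_sets optional `gene_sets` collection for the pathway filter.
#' @param target_genes drug-target gene ids anchoring the pathway filter
#'   (required when `gene_sets` is given).
#' @param network optional `interaction_network` for the network filter.
#' @param control a [sig_control()].
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @return an object of class `drugsig` with, among others, `signature`
#'   (the selected genes), `importances` (normalized to sum 1), `model`
#'   (final fitted handle), `trace` (elimination audit table), `screen`,
#'   `relief`, `boruta`, and `counts` (the funnel log).
#' @seealso [predict.drugsig()], [predict_ic50()], [variable_importance()]
#' @export
derive_signature <- function(expression, sensitivity, gene_sets = NULL,
                             target_genes = NULL, network = NULL,
                             control = sig_control(), seed = 1L) {
  stopifnot(inherits(expression, "expr_matrix"),
            inherits(sensitivity, "sens_table"),
            inherits(control, "sig_control"))
  seed <- as.integer(seed)
  if (!is.null(control$exclude_lineage) &&
      any(sensitivity$lineage == control$exclude_lineage))
    sensitivity <- exclude_lineage(sensitivity, control$exclude_lineage)
  al <- align_samples(expression, sensitivity)
  expr <- al$expression; sens <- al$sensitivity
  y <- sens$neglog10
  counts <- c(genes_input = nrow(expr$values), samples = ncol(expr$values))

  screen <- pearson_screen(expr, y)
  sig_genes <- select_significant(screen, control$alpha_corr)
  counts["correlated"] <- length(sig_genes)
  if (length(sig_genes) < 2L)
    stop("fewer than 2 genes pass the correlation screen")

  filtered <- sig_genes
  if (!is.null(gene_sets) || !is.null(network)) {
    path_keep <- if (!is.null(gene_sets)) {
      if (is.null(target_genes))
        stop("target_genes required when gene_sets are supplied")
      pathway_filter(sig_genes, gene_sets, target_genes)
    }
    net_keep <- if (!is.null(network))
      network_filter(sig_genes, network, rownames(expr$values))
    both <- Filter(Negate(is.null), list(path_keep, net_keep))
    filtered <- if (control$combine_filters == "union")
      Reduce(union, both) else Reduce(intersect, both)
    # funnel stays inside the screened set except for network neighbors,
    # which must at least be measured genes
    filtered <- filtered[filtered %in% rownames(expr$values)]
    if (length(filtered) < 2L)
      stop("fewer than 2 genes survive the biological filters")
  }
  counts["filtered"] <- length(filtered)

  relief <- relieff_rank(expr$values[filtered, , drop = FALSE], y,
                         k_neighbors = control$relief_k, seed = seed + 1L)
  top <- take_top(relief, control$top_n_relief)
  counts["relief_top"] <- length(top)

  X <- t(expr$values[top, , drop = FALSE])
  boruta <- boruta_select(X, y, alpha = control$alpha_boruta,
                          max_iter = control$boruta_max_iter,
                          spec = model_spec("random_forest",
                                            n_trees = control$boruta_trees,
                                            seed = seed + 2L))
  confirmed <- boruta$confirmed
  counts["confirmed"] <- length(confirmed)
  if (length(confirmed) == 0L)
    stop("Boruta confirmed no genes; cannot build a signature")

  holdout_size <- control$holdout_size
  if (is.null(holdout_size))
    holdout_size <- max(1L, round(nrow(X) * 11 / 52))

  if (length(confirmed) >= 2L) {
    elim <- backward_eliminate(X[, confirmed, drop = FALSE], y,
                               rank_order = relief$gene,
                               tune_grid = control$tune_grid,
                               cv_repeats = control$cv_repeats,
                               cv_folds = control$cv_folds,
                               holdout_size = holdout_size,
                               strata = sens$tumor_type,
                               criterion_on = control$criterion_on,
                               seed = seed + 3L)
    signature <- elim$signature
    best_spec <- elim$best_spec
    trace <- elim$trace
    holdout_idx <- elim$holdout_idx
  } else {
    message("derive_signature: single confirmed gene; skipping elimination")
    signature <- confirmed
    best_spec <- model_spec("gbtree",
                            n_trees = control$tune_grid$n_trees[1],
                            max_depth = 1L, eta = control$tune_grid$eta[1],
                            seed = seed + 3L)
    trace <- NULL
    holdout_idx <- integer()
  }
  counts["signature"] <- length(signature)
  message(sprintf(
    "derive_signature funnel: %d genes -> %d correlated -> %d filtered -> %d ranked -> %d confirmed -> %d signature",
    counts["genes_input"], counts["correlated"], counts["filtered"],
    counts["relief_top"], counts["confirmed"], counts["signature"]))

  # final model: full training cohort, winning hyperparameters
  model <- fit_regressor(X[, signature, drop = FALSE], y, best_spec)
  imp <- raw_importance(model)
  importances <- if (sum(imp) > 0) imp / sum(imp)
    else stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  ord <- order(-importances, names(importances))
  importances <- importances[ord]

  structure(list(signature = signature, model = model,
                 importances = importances, trace = trace,
                 screen = screen, relief = relief, boruta = boruta,
                 holdout_idx = holdout_idx, counts = counts,
                 train_samples = sens$sample_id, train_y = y,
                 train_X = X[, signature, drop = FALSE],
                 control = control, seed = seed),
            class = "drugsig")
}

#' @export
print.drugsig <- function(x, ...) {
  cat(sprintf("Drug-sensitivity signature: %d genes\n", length(x$signature)))
  cat("  ", paste(x$signature, collapse = ", "), "\n", sep = "")
  cat(sprintf("Top gene by importance: %s (%.1f%% of total)\n",
              names(x$importances)[1], 100 * x$importances[1]))
  cat("Funnel:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                       collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.drugsig <- function(object, ...) {
  print(object)
  cat("\nNormalized variable importances:\n")
  print(round(object$importances, 4))
  if (!is.null(object$trace)) {
    b <- which(object$trace$step == attr_best(object))
    cat(sprintf("\nSelected at elimination step %d (criterion %.3f = twofold %.3f + fourfold %.3f on %d holdout samples)\n",
                object$trace$step[b], object$trace$criterion[b],
                object$trace$twofold[b], object$trace$fourfold[b],
                length(object$holdout_idx)))
  }
  invisible(object)
}

attr_best <- function(object) {
  tr <- object$trace
  tr$step[order(-tr$criterion, tr$n_genes)[1]]
}

#' @export
coef.drugsig <- function(object, ...) object$importances

#' Predict \eqn{-\log_{10}}(M) sensitivity for new expression data
#'
#' @param object a fitted `drugsig`.
#' @param newdata an `expr_matrix` or genes x samples matrix containing all
#'   signature genes.
#' @param type `"neglog10"` (default) or `"molar"`.
#' @param ... unused.
#' @return named numeric vector of predictions, one per sample.
#' @export
predict.drugsig <- function(object, newdata, type = c("neglog10", "molar"),
                            ...) {
  type <- match.arg(type)
  vals <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  missing <- setdiff(object$signature, rownames(vals))
  if (length(missing))
    stop("missing signature gene(s) in new data: ",
         paste(missing, collapse = ", "))
  pred <- predict(object$model, t(vals[object$signature, , drop = FALSE]))
  names(pred) <- colnames(vals)
  if (type == "molar") 10^(-pred) else pred
}

#' @export
fitted.drugsig <- function(object, ...) {
  stats::setNames(predict(object$model, object$train_X),
                  object$train_samples)
}

#' @export
residuals.drugsig <- function(object, ...) {
  # in-sample residuals on the -log10(M) scale (optimistic; for diagnostics)
  stats::setNames(object$train_y - unname(fitted(object)),
                  object$train_samples)
}

#' @export
plot.drugsig <- function(x, ...) {
  if (is.null(x$trace)) {
    graphics::barplot(rev(x$importances), horiz = TRUE, las = 1,
                      xlab = "normalized importance",
                      main = "Signature importances")
    return(invisible(x))
  }
  tr <- x$trace
  graphics::plot(tr$n_genes, tr$criterion, type = "b", pch = 16,
                 xlab = "genes in model",
                 ylab = "two-fold + four-fold holdout accuracy",
                 main = "Backward elimination trace", ...)
  b <- order(-tr$criterion, tr$n_genes)[1]
  graphics::points(tr$n_genes[b], tr$criterion[b], col = 2, cex = 2)
  invisible(x)
}

#' Full prediction result with z-scores and responder calls
#'
#' Applies a fitted signature model to an expression cohort and returns the
#' per-sample prediction on both scales, the within-cohort z-score of
#' predicted sensitivity, and the sensitive/resistant call (z > 0 =
#' sensitive).
#'
#' @param object a fitted `drugsig`.
#' @param expression an `expr_matrix` containing all signature genes.
#' @return data.frame of class `prediction_result` with columns
#'   `sample_id`, `pred_neglog10`, `pred_ic50_molar`, `z`, `class`, plus
#'   `tumor_type`/`lineage` when the matrix carries annotations.
#' @export
predict_ic50 <- function(object, expression) {
  pred <- predict(object, expression)
  if (length(pred) < 2L)
    stop("z-score undefined for a single-sample cohort; use predict() for raw values")
  out <- data.frame(sample_id = names(pred), pred_neglog10 = unname(pred),
                    pred_ic50_molar = 10^(-unname(pred)),
                    stringsAsFactors = FALSE)
  if (inherits(expression, "expr_matrix") && !is.null(expression$annotations)) {
    out$tumor_type <- expression$annotations$tumor_type
    out$lineage <- expression$annotations$lineage
  }
  out <- zscore_classify(out)
  structure(out, class = c("prediction_result", "data.frame"))
}

#' Normalized variable-importance table of a fitted signature model
#'
#' @param object a fitted `drugsig`.
#' @return data.frame with columns `gene` and `importance` (nonnegative,
#'   summing to 1), ordered by decreasing importance with lexicographic
#'   tie-breaks.
#' @export
variable_importance <- function(object) {
  if (!inherits(object, "drugsig") || is.null(object$model))
    stop("variable_importance requires a fitted drugsig model")
  data.frame(gene = names(object$importances),
             importance = unname(object$importances),
             stringsAsFactors = FALSE)
}
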