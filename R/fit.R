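#' Specification of a tree-ensemble regressor
#'
#' @param kind `"gbtree"` (gradient-boosted trees, the default for the
#'   regression stages) or `"random_forest"` (used inside Boruta).
#' @param n_trees boosting rounds / forest size (default 300).
#' @param max_depth tree depth (default 2; depth 1 = additive stump
#'   boosting, well suited to mostly-additive expression signals).
#' @param eta learning rate for boosting (ignored by random forest).
#' @param seed integer seed for any stochastic training components.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(kind = c("gbtree", "random_forest"), n_trees = 300L,
                       max_depth = 2L, eta = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_trees >= 1, max_depth >= 1, eta > 0)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), eta = eta,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a tree-ensemble regressor
#'
#' Thin wrapper giving both ensemble kinds the same handle interface:
#' `predict()` on new sample x gene matrices and [raw_importance()] per
#' feature. Training is deterministic given the spec's seed (boosting runs
#' single-threaded without row/column subsampling; the forest is seeded).
#'
#' @param X numeric samples x genes matrix with column names.
#' @param y numeric target, one value per row of `X`.
#' @param spec a [model_spec()].
#' @return a fitted handle of class `sig_regressor`.
#' @export
fit_regressor <- function(X, y, spec = model_spec()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have gene column names")
  if (nrow(X) != length(y)) stop("X and y are misaligned")
  if (nrow(X) < 5L) stop("need at least 5 samples to fit")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(y) == 0) {
    warning("degenerate target (zero variance); fitting a constant predictor")
    return(structure(list(kind = "constant", constant = y[1],
                          features = colnames(X), spec = spec),
                     class = "sig_regressor"))
  }
  fit <- if (spec$kind == "gbtree") {
    xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                     max_depth = spec$max_depth,
                                     eta = spec$eta, nthread = 1,
                                     seed = spec$seed),
                       data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
                       nrounds = spec$n_trees, verbose = 0)
  } else {
    df <- data.frame(..y.. = y, X, check.names = FALSE)
    ranger::ranger(dependent.variable.name = "..y..", data = df,
                   num.trees = spec$n_trees, importance = "impurity",
                   seed = spec$seed, num.threads = 1,
                   respect.unordered.factors = TRUE)
  }
  structure(list(kind = spec$kind, fit = fit, features = colnames(X),
                 spec = spec),
            class = "sig_regressor")
}

#' @export
predict.sig_regressor <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("missing signature gene(s) in new data: ",
         paste(missing, collapse = ", "))
  newdata <- newdata[, object$features, drop = FALSE]
  switch(object$kind,
         constant = rep(object$constant, nrow(newdata)),
         gbtree = predict(object$fit,
                          xgboost::xgb.DMatrix(newdata, nthread = 1)),
         random_forest = stats::predict(object$fit,
                                        data = as.data.frame(newdata),
                                        num.threads = 1)$predictions)
}

#' Raw per-feature importance of a fitted ensemble
#'
#' Gain importance for boosted trees, impurity importance for the forest;
#' features never used in a split get 0. Order follows the training
#' feature order.
#'
#' @param object a `sig_regressor`.
#' @return named numeric vector over all training features.
#' @export
raw_importance <- function(object) {
  stopifnot(inherits(object, "sig_regressor"))
  imp <- stats::setNames(numeric(length(object$features)), object$features)
  if (object$kind == "constant") return(imp)
  if (object$kind == "gbtree") {
    if (length(object$features) == 1L) return(imp + 1)  # all gain on one gene
    tab <- xgboost::xgb.importance(model = object$fit)
    if (!is.null(tab) && nrow(tab)) imp[tab$Feature] <- tab$Gain
  } else {
    v <- object$fit$variable.importance
    imp[names(v)] <- pmax(v, 0)
  }
  imp
}
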