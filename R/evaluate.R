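#' Fold-change prediction accuracy
#'
#' Fraction of samples whose predicted and actual IC50 agree within a factor
#' of `k`: \eqn{\max(p, a)/\min(p, a) \le k}, boundary inclusive (a
#' prediction exactly k-fold off still counts as within k fold). Symmetric
#' in its arguments and invariant to a common rescaling.
#'
#' @param predicted,actual positive IC50 vectors (Molar), equal length.
#' @param k fold threshold (e.g. 2 or 4).
#' @return fraction in \[0, 1\].
#' @export
fold_accuracy <- function(predicted, actual, k) {
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  if (any(predicted <= 0) || any(actual <= 0))
    stop("IC50 values must be strictly positive")
  stopifnot(k >= 1)
  ratio <- pmax(predicted, actual) / pmin(predicted, actual)
  mean(ratio <= k * (1 + 1e-9))   # tolerance keeps the exact boundary inclusive
}

#' Pearson agreement between predicted and actual IC50
#'
#' Correlation computed on the \eqn{-\log_{10}}(M) scale, with the same
#' t-transform p-value as the screening stage.
#'
#' @param predicted,actual positive IC50 vectors (Molar), n >= 4.
#' @return list with `r` and `p`.
#' @export
pearson_agreement <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  n <- length(actual)
  if (n < 4L) stop("need at least 4 pairs")
  x <- -log10(predicted); y <- -log10(actual)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance vector: correlation undefined")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  list(r = r, p = p)
}

#' Root mean squared error
#'
#' @param predicted,actual numeric vectors on the \eqn{-\log_{10}}(M) scale.
#' @return RMSE in \eqn{-\log_{10}}(M) units.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  sqrt(mean((predicted - actual)^2))
}

#' Full agreement report between predicted and actual IC50
#'
#' @param predicted,actual positive IC50 vectors (Molar).
#' @return list of class `agreement_report`: `n`, `twofold`, `fourfold`
#'   (fractions), `r`, `p`, `rmse` (on the \eqn{-\log_{10}} scale).
#' @export
agreement_report <- function(predicted, actual) {
  pa <- pearson_agreement(predicted, actual)
  structure(list(n = length(actual),
                 twofold = fold_accuracy(predicted, actual, 2),
                 fourfold = fold_accuracy(predicted, actual, 4),
                 r = pa$r, p = pa$p,
                 rmse = rmse(-log10(predicted), -log10(actual))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement on %d samples:\n", x$n))
  cat(sprintf("  two-fold accuracy : %.2f%%\n", 100 * x$twofold))
  cat(sprintf("  four-fold accuracy: %.2f%%\n", 100 * x$fourfold))
  cat(sprintf("  Pearson r = %.4f (p = %.3g)\n", x$r, x$p))
  cat(sprintf("  RMSE = %.4f (-log10 M)\n", x$rmse))
  invisible(x)
}

#' Classify samples as sensitive or resistant by cohort z-score
#'
#' Standardizes the predicted sensitivity (\eqn{-\log_{10}} Molar, higher =
#' more sensitive) within the cohort; samples with z > 0 are called
#' sensitive, z <= 0 resistant (strict ">" for the sensitive call).
#'
#' @param predictions a `prediction_result` from [predict_ic50()], or a
#'   data.frame with a `pred_neglog10` column.
#' @return the input with `z` and `class` columns (re)populated.
#' @export
zscore_classify <- function(predictions) {
  y <- predictions$pred_neglog10
  if (length(y) < 2L)
    stop("z-score undefined for a single-sample cohort; use the raw predictions")
  if (stats::sd(y) == 0)
    stop("z-score undefined: all predictions identical; use the raw predictions")
  z <- (y - mean(y)) / stats::sd(y)
  predictions$z <- z
  predictions$class <- ifelse(z > 0, "sensitive", "resistant")
  message(sprintf("zscore_classify: %d sensitive, %d resistant",
                  sum(z > 0), sum(z <= 0)))
  predictions
}

#' Classify tumor types by their fraction of predicted-sensitive lines
#'
#' A tumor type is called sensitive if strictly more than `threshold`
#' percent of its lines are predicted sensitive, resistant if strictly more
#' than `threshold` percent are predicted resistant, otherwise mixed.
#' Samples with a missing/empty tumor-type label are excluded (count
#' reported).
#'
#' @param predictions a classified `prediction_result` (needs `class` and
#'   `tumor_type` columns).
#' @param threshold percentage cut (default 60).
#' @return data.frame of class `tumor_type_summary`: `tumor_type`, `n`,
#'   `pct_sensitive`, `class`.
#' @export
tumor_type_classify <- function(predictions, threshold = 60) {
  tt <- predictions$tumor_type
  unlab <- is.na(tt) | !nzchar(tt)
  if (any(unlab)) {
    message("tumor_type_classify: excluded ", sum(unlab), " unlabeled sample(s)")
    predictions <- predictions[!unlab, , drop = FALSE]
    tt <- tt[!unlab]
  }
  types <- sort(unique(tt))
  res <- lapply(types, function(ty) {
    cls <- predictions$class[tt == ty]
    pct <- 100 * mean(cls == "sensitive")
    call <- if (pct > threshold) "sensitive"
            else if (100 - pct > threshold) "resistant" else "mixed"
    data.frame(tumor_type = ty, n = length(cls), pct_sensitive = pct,
               class = call, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            class = c("tumor_type_summary", "data.frame"))
}
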