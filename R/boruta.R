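#' Boruta shadow-feature selection
#'
#' Classic shadow scheme over a random-forest importance measure: each
#' iteration appends an independently permuted ("shadow") copy of every
#' candidate feature, fits the forest, and scores a hit for every real
#' feature whose importance exceeds the maximum shadow importance. After
#' each iteration a two-sided binomial test on the hit counts (p = 0.5
#' under the null), Bonferroni-corrected across the candidate features,
#' confirms features with significantly many hits and rejects those with
#' significantly few; rejected features leave the shadow race. Features
#' still undecided at `max_iter` are `tentative`.
#'
#' @param X samples x genes matrix with column names.
#' @param y continuous target.
#' @param alpha significance level of the binomial test (default 0.05,
#'   Bonferroni-corrected by the number of candidates).
#' @param max_iter maximum shadow iterations (>= 5; default 50).
#' @param spec a [model_spec()]; the `kind` is forced to random forest.
#' @return list of class `boruta_decision`: `decisions` (data.frame gene /
#'   verdict / hits / iterations), and the per-verdict gene vectors
#'   `confirmed`, `rejected`, `tentative`.
#' @export
boruta_select <- function(X, y, alpha = 0.05, max_iter = 50L,
                          spec = model_spec("random_forest", n_trees = 300L)) {
  if (!is.matrix(X)) X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 candidate genes")
  if (max_iter < 5L) stop("max_iter < 5: the binomial test is underpowered")
  genes <- colnames(X)
  verdict <- stats::setNames(rep("tentative", p), genes)
  hits <- stats::setNames(integer(p), genes)
  iters <- stats::setNames(integer(p), genes)
  thresh <- alpha / p   # Bonferroni across features

  with_seed(spec$seed, {
    for (it in seq_len(max_iter)) {
      open <- names(verdict)[verdict != "rejected"]
      if (!any(verdict == "tentative")) break
      Xr <- X[, open, drop = FALSE]
      Xs <- apply(Xr, 2L, sample)
      colnames(Xs) <- paste0("shadow_", open)
      fit_seed <- spec$seed + it
      fit <- fit_regressor(cbind(Xr, Xs), y,
                           model_spec("random_forest", n_trees = spec$n_trees,
                                      seed = fit_seed))
      imp <- raw_importance(fit)
      shadow_max <- max(imp[paste0("shadow_", open)])
      hit <- imp[open] > shadow_max
      hits[open] <- hits[open] + as.integer(hit)
      iters[open] <- it
      und <- names(verdict)[verdict == "tentative"]
      p_hi <- stats::pbinom(hits[und] - 1L, it, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[und], it, 0.5)
      verdict[und[p_hi <= thresh]] <- "confirmed"
      verdict[und[p_lo <= thresh]] <- "rejected"
    }
  })
  dec <- data.frame(gene = genes, verdict = unname(verdict),
                    hits = unname(hits), iterations = unname(iters),
                    stringsAsFactors = FALSE)
  structure(list(decisions = dec,
                 confirmed = genes[verdict == "confirmed"],
                 rejected = genes[verdict == "rejected"],
                 tentative = genes[verdict == "tentative"]),
            class = "boruta_decision")
}

#' @export
print.boruta_decision <- function(x, ...) {
  cat(sprintf("Boruta: %d confirmed, %d rejected, %d tentative (of %d candidates)\n",
              length(x$confirmed), length(x$rejected), length(x$tentative),
              nrow(x$decisions)))
  invisible(x)
}
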