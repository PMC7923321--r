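#' Pearson correlation screen of every gene against drug sensitivity
#'
#' Computes the product-moment correlation of each gene's expression with
#' the \eqn{-\log_{10}}(M) sensitivity target, with the two-sided p-value
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees
#' of freedom. Genes with constant expression have undefined correlation and
#' are excluded (reported via `message()`).
#'
#' @param expr an `expr_matrix` (or plain genes x samples matrix).
#' @param y numeric \eqn{-\log_{10}}(M) sensitivity, aligned with the
#'   columns of `expr`.
#' @return data.frame of class `correlation_result` with columns `gene`,
#'   `r`, `p`, `n`, `sign`, ordered as the input genes.
#' @export
pearson_screen <- function(expr, y) {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (ncol(vals) != length(y))
    stop("expression and target are misaligned: ", ncol(vals),
         " samples vs ", length(y), " target values")
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples for the correlation screen")
  sds <- apply(vals, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    message("pearson_screen: excluded ", sum(const),
            " constant-expression gene(s)")
  use <- vals[!const, , drop = FALSE]
  yc <- y - mean(y)
  xc <- use - rowMeans(use)
  r <- drop(xc %*% yc) / (sqrt(rowSums(xc^2)) * sqrt(sum(yc^2)))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)   # report underflow as smallest positive
  structure(data.frame(gene = rownames(use), r = r, p = p, n = n,
                       sign = ifelse(r >= 0, "positive", "negative"),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("correlation_result", "data.frame"))
}

#' Genes significantly correlated with sensitivity
#'
#' Inclusive threshold (p <= alpha); both correlation signs are retained.
#'
#' @param corr a `correlation_result`.
#' @param alpha significance level (default 0.05).
#' @return character vector of gene ids.
#' @export
select_significant <- function(corr, alpha = 0.05) {
  corr$gene[corr$p <= alpha]
}

#' Top positively and negatively correlated genes
#'
#' @param corr a `correlation_result`.
#' @param n_pos,n_neg how many genes from each tail of the correlation
#'   distribution (e.g. 10/10 for a top-20 heatmap panel, 100/100 for
#'   overlap analyses). Requests beyond the available count of a sign
#'   truncate with a warning.
#' @return character vector: `n_pos` genes with largest r followed by
#'   `n_neg` with smallest r.
#' @export
select_top_correlates <- function(corr, n_pos = 10L, n_neg = 10L) {
  ord <- order(-corr$r, corr$gene)
  pos <- corr$gene[ord][corr$r[ord] > 0]
  ordn <- order(corr$r, corr$gene)
  neg <- corr$gene[ordn][corr$r[ordn] < 0]
  if (length(pos) < n_pos)
    warning("only ", length(pos), " positively correlated genes available")
  if (length(neg) < n_neg)
    warning("only ", length(neg), " negatively correlated genes available")
  c(utils::head(pos, n_pos), utils::head(neg, n_neg))
}

#' Retain genes sharing a pathway with the drug's target genes
#'
#' A candidate survives if it co-occurs in at least one gene set with at
#' least one target gene — "related to the drug's target pathway".
#'
#' @param genes candidate gene ids.
#' @param sets a `gene_sets` collection.
#' @param target_genes nonempty character vector of drug-target gene ids.
#' @return the retained subset of `genes`, in input order.
#' @export
pathway_filter <- function(genes, sets, target_genes) {
  if (length(target_genes) == 0L) stop("target_genes must be nonempty")
  with_target <- vapply(sets, function(s) any(target_genes %in% s), FALSE)
  if (!any(with_target))
    stop("no target gene found in any gene set")
  related <- unique(unlist(sets[with_target], use.names = FALSE))
  genes[genes %in% related]
}

#' Expand a gene list by its direct network neighbors
#'
#' Returns the input genes plus every gene at graph distance 1 in the
#' interaction network, restricted to the measured gene universe.
#'
#' @param genes input gene ids.
#' @param net an `interaction_network`.
#' @param measured_genes gene universe to restrict to (e.g. rownames of the
#'   expression matrix); `NULL` for no restriction.
#' @return character vector (input order first, then new neighbors).
#' @export
network_filter <- function(genes, net, measured_genes = NULL) {
  nb <- c(net$to[net$from %in% genes], net$from[net$to %in% genes])
  out <- unique(c(genes, nb))
  if (!is.null(measured_genes)) out <- out[out %in% measured_genes]
  out
}

#' First n genes of a ranked list
#'
#' @param ranked a `ranked_genes` data.frame from [relieff_rank()].
#' @param n how many to keep (default 100, the funnel's hand-off size to the
#'   prediction module). Shorter lists are returned whole with a warning.
#' @return character vector of gene ids.
#' @export
take_top <- function(ranked, n = 100L) {
  if (nrow(ranked) < n)
    warning("only ", nrow(ranked), " ranked genes available (requested ", n, ")")
  utils::head(ranked$gene, n)
}
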