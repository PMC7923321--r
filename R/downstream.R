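#' Hierarchical clustering of an expression submatrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage —
#' the standard heatmap-dendrogram combination. Either axis can be
#' clustered; genes may be standardized first (the usual heatmap display
#' scaling).
#'
#' @param expr an `expr_matrix` or genes x samples matrix (typically
#'   restricted to selected genes/samples).
#' @param axis `"samples"` (default) or `"genes"`.
#' @param scale_genes standardize each gene across samples before
#'   clustering (default TRUE when clustering samples).
#' @return list of class `clustering_result`: `hclust` (the stats::hclust
#'   tree), `order` (leaf order labels), and `cut(k)` via [cutree].
#' @export
hierarchical_cluster <- function(expr, axis = c("samples", "genes"),
                                 scale_genes = axis[1] == "samples") {
  axis <- match.arg(axis)
  vals <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (isTRUE(scale_genes)) {
    sds <- apply(vals, 1L, stats::sd)
    sds[sds == 0] <- 1
    vals <- (vals - rowMeans(vals)) / sds
  }
  items <- if (axis == "samples") t(vals) else vals
  if (nrow(items) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(items, method = "euclidean"),
                      method = "complete")
  structure(list(hclust = hc, order = hc$labels[hc$order], axis = axis),
            class = "clustering_result")
}

#' Cluster labels at a requested cut
#' @param clustering a `clustering_result`.
#' @param k number of clusters.
#' @return named integer vector of cluster labels.
#' @export
cut_clusters <- function(clustering, k = 2L) {
  stats::cutree(clustering$hclust, k = k)
}

#' Export a dendrogram as a Newick tree
#' @param clustering a `clustering_result`.
#' @param path output path.
#' @export
export_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Agreement between a 2-cluster cut and known sensitivity groups
#'
#' Matches the two clusters to the two true labels in whichever assignment
#' agrees best and returns the fraction of correctly grouped samples —
#' the "all-but-one cell line correctly grouped" style of summary.
#'
#' @param clusters integer cluster labels from a cut at 2 (named by
#'   sample), or a `clustering_result` (cut at 2 internally).
#' @param true_labels two-level factor/character vector of the known
#'   sensitive/resistant labels, in the same sample order (or named).
#' @return agreement fraction in \[0, 1\].
#' @export
coclustering_agreement <- function(clusters, true_labels) {
  if (inherits(clusters, "clustering_result"))
    clusters <- cut_clusters(clusters, 2L)
  if (!is.null(names(clusters)) && !is.null(names(true_labels)))
    true_labels <- true_labels[names(clusters)]
  lab <- as.character(true_labels)
  lv <- unique(lab)
  if (length(lv) != 2L) stop("true_labels must have exactly 2 levels")
  a <- mean((clusters == 1) == (lab == lv[1]))
  max(a, 1 - a)
}

#' Wilcoxon rank-sum test between two expression groups
#'
#' Two-sided rank-sum test as used for differential expression between
#' sensitive and resistant lines: exact when both groups have <= 10
#' observations and no ties, otherwise the normal approximation with
#' midranks and continuity correction.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @return list with `statistic` (the rank-sum U statistic) and `p`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  exact_ok <- length(group_a) <= 10L && length(group_b) <= 10L &&
    !anyDuplicated(c(group_a, group_b))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact_ok,
                       correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Overlap between two gene lists
#'
#' @param list_a,list_b character vectors (duplicates ignored).
#' @return list: `intersection` (genes), `fraction_a` = |A∩B|/|A|,
#'   `fraction_b` = |A∩B|/|B|.
#' @export
list_overlap <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  i <- intersect(a, b)
  list(intersection = i,
       fraction_a = if (length(a)) length(i) / length(a) else 0,
       fraction_b = if (length(b)) length(i) / length(b) else 0)
}

#' Hypergeometric gene-set enrichment with BH FDR control
#'
#' Upper-tail hypergeometric test of each set's overlap with the query
#' (equivalent to the one-sided Fisher exact test), Benjamini-Hochberg
#' adjusted across sets, flagged significant at `fdr_threshold`.
#' Query genes outside the universe are dropped with a warning; set
#' members are intersected with the universe.
#'
#' @param query character vector of genes of interest (nonempty).
#' @param sets a `gene_sets` collection.
#' @param universe character vector of all assayed genes.
#' @param fdr_threshold FDR significance cut (default 0.05).
#' @return data.frame of class `enrichment_result`: `set`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `fdr`, `significant`.
#' @export
enrichment_test <- function(query, sets, universe, fdr_threshold = 0.05) {
  if (length(query) == 0L) stop("empty query")
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out)) {
    warning("dropped ", length(out), " query gene(s) outside the universe")
    query <- intersect(query, universe)
    if (length(query) == 0L) stop("empty query after universe restriction")
  }
  N <- length(universe); q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    # P(X >= k) for X ~ Hypergeom(N, |s|, q)
    p <- stats::phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s), query_size = q,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= fdr_threshold
  structure(res[order(res$p, res$set), , drop = FALSE],
            class = c("enrichment_result", "data.frame"))
}
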