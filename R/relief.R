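#' RReliefF feature ranking for a continuous target
#'
#' Relief-family ranking adapted to regression: for every sample, the k
#' nearest neighbors (Manhattan distance on min-max-scaled features) vote on
#' how often a feature's value difference co-occurs with a target
#' difference. With \eqn{N_{dC}}, \eqn{N_{dA}[f]} and \eqn{N_{dC \wedge dA}[f]}
#' the accumulated (neighbor-weighted) probabilities of a target change, a
#' feature change, and both, the weight is
#' \deqn{W[f] = \frac{N_{dC \wedge dA}[f]}{N_{dC}} -
#'       \frac{N_{dA}[f] - N_{dC \wedge dA}[f]}{m - N_{dC}}.}
#' Every sample is used as a reference instance (deterministic; the `seed`
#' only matters when `n_iterations` subsamples), and neighbors carry uniform
#' weight 1/k. Feature and target differences are normalized by their
#' min-max range. Ties in the final ordering are broken lexicographically
#' by gene id.
#'
#' @param expr an `expr_matrix` or genes x samples matrix, restricted to the
#'   candidate genes.
#' @param y continuous \eqn{-\log_{10}}(M) target aligned with samples.
#' @param k_neighbors nearest neighbors per reference instance (default 10).
#' @param n_iterations reference instances to use; `NULL` (default) = all
#'   samples.
#' @param seed seed used only when subsampling reference instances.
#' @return data.frame of class `ranked_genes` with columns `gene`, `weight`,
#'   ordered by nonincreasing weight.
#' @export
relieff_rank <- function(expr, y, k_neighbors = 10L, n_iterations = NULL,
                         seed = 1L) {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else expr
  n <- ncol(vals)
  if (n != length(y)) stop("expression and target are misaligned")
  if (n < k_neighbors + 1L)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1L, " samples")
  p <- nrow(vals)
  # min-max scale features (rows) and target to [0, 1]
  rng <- apply(vals, 1L, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  X <- (vals - rng[1, ]) / span                      # p x n
  yr <- range(y)
  dy_scale <- if (diff(yr) == 0) 1 else diff(yr)
  ys <- (y - yr[1]) / dy_scale

  refs <- seq_len(n)
  if (!is.null(n_iterations) && n_iterations < n)
    refs <- with_seed(seed, sample.int(n, n_iterations))

  D <- as.matrix(stats::dist(t(X), method = "manhattan"))
  ndc <- 0
  nda <- numeric(p)
  ndcda <- numeric(p)
  w_nb <- 1 / k_neighbors
  for (i in refs) {
    ord <- order(D[i, ], decreasing = FALSE)
    nb <- setdiff(ord, i)[seq_len(k_neighbors)]
    for (j in nb) {
      d_y <- abs(ys[i] - ys[j])
      d_f <- abs(X[, i] - X[, j])
      ndc <- ndc + w_nb * d_y
      nda <- nda + w_nb * d_f
      ndcda <- ndcda + w_nb * d_y * d_f
    }
  }
  m <- length(refs)
  w <- if (ndc == 0) rep(0, p) else ndcda / ndc - (nda - ndcda) / (m - ndc)
  genes <- rownames(vals)
  ord <- order(-w, genes)
  structure(data.frame(gene = genes[ord], weight = w[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_genes", "data.frame"))
}
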