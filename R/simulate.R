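#' Configuration for the synthetic cell-line panel generator
#'
#' Describes the generative law: independent per-gene log2 expression
#' (gene means ~ Uniform(4, 12), sds ~ Uniform(0.5, 2)), and a continuous
#' sensitivity target
#' \deqn{y = -\log_{10} IC50 = \beta_0 + \sum_j \beta_j z_j + \delta_{blood} + \varepsilon,}
#' where \eqn{z_j} is the causal gene's expression standardized by its
#' generative mean and sd, \eqn{\varepsilon \sim N(0, noise\_sd^2)}, and
#' blood-lineage samples receive a negative offset (resistance). Train and
#' blind partitions follow the identical law; blood lines appear only in the
#' training cohort (the blind panel is solid-tumor only).
#'
#' The default causal architecture is a single dominant driver
#' (\eqn{\beta = 1.5}) — the bioactivating-enzyme situation where one gene
#' carries the sensitivity signal; weaker secondary causal genes can be
#' added via `n_secondary`/`beta_secondary` to stress multi-gene selection.
#'
#' @param n_train solid-tumor training samples (default 52).
#' @param n_blind independent blind-set samples (default 37).
#' @param n_genes genes in the panel (default 2000).
#' @param beta_dominant effect size of the dominant driver on the
#'   \eqn{-\log_{10}}(M) scale (default 1.5).
#' @param n_secondary number of secondary causal genes (default 0).
#' @param beta_secondary effect size of each secondary causal gene
#'   (default 0.4).
#' @param beta0 intercept; default 6.5 so typical IC50s fall in the
#'   ~14 nM - 36 uM band.
#' @param noise_sd sd of the additive Gaussian noise on the target
#'   (default 0.3).
#' @param resistant_lineage_fraction fraction of the training cohort that is
#'   blood-lineage (default 6/58: 6 blood lines alongside 52 solid).
#' @param blood_offset additive offset applied to blood-lineage targets;
#'   negative = more resistant (default -1.5).
#' @param n_tumor_types number of solid tumor-type labels (default 7).
#' @param block_rho optional correlation in (0,1): each causal gene gets
#'   `block_size - 1` passenger genes correlated with it at this level, to
#'   stress collinearity handling. `NULL` (default) keeps genes independent.
#' @param block_size genes per correlated block when `block_rho` is set.
#' @param seed integer random seed; the whole dataset is a deterministic
#'   function of the config including this seed.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_train = 52L, n_blind = 37L, n_genes = 2000L,
                             beta_dominant = 1.5, n_secondary = 0L,
                             beta_secondary = 0.4, beta0 = 6.5,
                             noise_sd = 0.3,
                             resistant_lineage_fraction = 6 / 58,
                             blood_offset = -1.5, n_tumor_types = 7L,
                             block_rho = NULL, block_size = 4L,
                             seed = 1L) {
  stopifnot(n_train >= 4, n_blind >= 2, n_genes >= 2,
            noise_sd >= 0, n_tumor_types >= 1,
            resistant_lineage_fraction >= 0, resistant_lineage_fraction < 1,
            n_secondary >= 0, 1 + n_secondary <= n_genes)
  if (!is.null(block_rho))
    stopifnot(block_rho > 0, block_rho < 1, block_size >= 2)
  structure(list(n_train = as.integer(n_train), n_blind = as.integer(n_blind),
                 n_genes = as.integer(n_genes), beta_dominant = beta_dominant,
                 n_secondary = as.integer(n_secondary),
                 beta_secondary = beta_secondary, beta0 = beta0,
                 noise_sd = noise_sd,
                 resistant_lineage_fraction = resistant_lineage_fraction,
                 blood_offset = blood_offset,
                 n_tumor_types = as.integer(n_tumor_types),
                 block_rho = block_rho, block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

solid_types <- c("breast", "cns", "colon", "lung", "melanoma", "ovarian",
                 "renal", "prostate", "pancreas")

#' Generate a synthetic expression / IC50 dataset with planted causal genes
#'
#' Draws a training cohort (solid lines plus a resistant blood-lineage
#' subgroup) and an independent blind cohort from the law described in
#' [generator_config()]. Gene ids are `G00001, ...`; causal gene positions
#' are drawn from the seed and recorded in the truth manifest.
#'
#' @param config a `generator_config`.
#' @return a list of class `synthetic_dataset` with elements `expression`,
#'   `sensitivity` (training cohort incl. blood lines), `blind_expression`,
#'   `blind_sensitivity`, and `truth` (list: data.frame of causal genes with
#'   effect sizes, `dominant_gene`, `noise_sd`, `beta0`, `blood_offset`).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    p <- config$n_genes
    n_blood <- round(config$resistant_lineage_fraction /
                     (1 - config$resistant_lineage_fraction) * config$n_train)
    n_tr <- config$n_train + n_blood
    n <- n_tr + config$n_blind
    gene_ids <- sprintf("G%05d", seq_len(p))
    gene_mean <- stats::runif(p, 4, 12)
    gene_sd <- stats::runif(p, 0.5, 2)
    n_causal <- 1L + config$n_secondary
    causal_idx <- sample.int(p, n_causal)
    beta <- c(config$beta_dominant,
              rep(config$beta_secondary, config$n_secondary))

    Z <- matrix(stats::rnorm(n * p), nrow = p, ncol = n)  # standardized scores
    if (!is.null(config$block_rho)) {
      # give each causal gene block_size-1 correlated passengers
      free <- setdiff(seq_len(p), causal_idx)
      for (ci in causal_idx) {
        k <- min(config$block_size - 1L, length(free))
        if (k == 0L) break
        pick <- free[seq_len(k)]
        free <- free[-seq_len(k)]
        r <- config$block_rho
        Z[pick, ] <- r * matrix(Z[ci, ], nrow = k, ncol = n, byrow = TRUE) +
          sqrt(1 - r^2) * Z[pick, , drop = FALSE]
      }
    }
    vals <- Z * gene_sd + gene_mean
    rownames(vals) <- gene_ids

    y <- config$beta0 + drop(crossprod(Z[causal_idx, , drop = FALSE], beta)) +
      stats::rnorm(n, 0, config$noise_sd)

    ids <- c(sprintf("TRAIN_%03d", seq_len(config$n_train)),
             if (n_blood) sprintf("BLOOD_%03d", seq_len(n_blood)),
             sprintf("BLIND_%03d", seq_len(config$n_blind)))
    lineage <- c(rep("solid", config$n_train), rep("blood", n_blood),
                 rep("solid", config$n_blind))
    types <- solid_types[seq_len(min(config$n_tumor_types, length(solid_types)))]
    tumor_type <- sample(types, n, replace = TRUE)
    tumor_type[lineage == "blood"] <- "leukemia"
    y[lineage == "blood"] <- y[lineage == "blood"] + config$blood_offset
    colnames(vals) <- ids

    ann <- data.frame(sample_id = ids, tumor_type = tumor_type,
                      lineage = lineage, stringsAsFactors = FALSE)
    tr <- seq_len(n_tr)
    bl <- n_tr + seq_len(config$n_blind)
    make_part <- function(idx) {
      list(expr = expression_matrix(vals[, idx, drop = FALSE],
                                    ann[idx, , drop = FALSE]),
           sens = sensitivity_table(ids[idx], 10^(-y[idx]),
                                    tumor_type[idx], lineage[idx]))
    }
    train <- make_part(tr)
    blind <- make_part(bl)
    truth <- list(causal = data.frame(gene = gene_ids[causal_idx],
                                      beta = beta,
                                      dominant = c(TRUE, rep(FALSE, config$n_secondary)),
                                      stringsAsFactors = FALSE),
                  dominant_gene = gene_ids[causal_idx[1]],
                  noise_sd = config$noise_sd, beta0 = config$beta0,
                  blood_offset = config$blood_offset)
    structure(list(expression = train$expr, sensitivity = train$sens,
                   blind_expression = blind$expr, blind_sensitivity = blind$sens,
                   truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes; train %d samples (%d blood), blind %d samples\n",
              nrow(x$expression$values), ncol(x$expression$values),
              sum(x$expression$annotations$lineage == "blood"),
              ncol(x$blind_expression$values)))
  cat("Causal genes:", paste(sprintf("%s (beta=%.2f)", x$truth$causal$gene,
                                     x$truth$causal$beta), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a random gene-set collection over a synthetic dataset
#'
#' Draws `n_sets` sets of `set_size` members from the dataset's gene
#' universe. With `include_causal_set`, one additional set contains all
#' causal genes — the analog of the drug's known target pathway.
#'
#' @param dataset a `synthetic_dataset`.
#' @param n_sets number of random sets.
#' @param set_size members per set.
#' @param include_causal_set add a set covering all causal genes.
#' @param seed random seed.
#' @return a `gene_sets` collection.
#' @export
generate_gene_sets <- function(dataset, n_sets = 50L, set_size = 20L,
                               include_causal_set = TRUE, seed = 1L) {
  stopifnot(n_sets >= 0, set_size >= 1)
  universe <- rownames(dataset$expression$values)
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
    if (include_causal_set) {
      extra <- unique(c(dataset$truth$causal$gene,
                        sample(universe, min(set_size, length(universe)))))
      sets <- c(sets, list(TARGET_PATHWAY = extra))
    }
    gene_set_collection(sets)
  })
}

#' Generate a sparse random interaction network over a synthetic dataset
#'
#' Erdos-Renyi style graph with expected mean degree `degree_mean`. With
#' `connect_causal`, all causal genes are additionally made mutual
#' neighbors (a connected target module).
#'
#' @param dataset a `synthetic_dataset`.
#' @param degree_mean expected mean degree (> 0).
#' @param connect_causal clique the causal genes.
#' @param seed random seed.
#' @return an `interaction_network`.
#' @export
generate_network <- function(dataset, degree_mean = 2, connect_causal = TRUE,
                             seed = 1L) {
  stopifnot(degree_mean > 0)
  genes <- rownames(dataset$expression$values)
  p <- length(genes)
  with_seed(seed, {
    n_edges <- stats::rpois(1, degree_mean * p / 2)
    a <- sample.int(p, n_edges, replace = TRUE)
    b <- sample.int(p, n_edges, replace = TRUE)
    keep <- a != b
    from <- genes[a[keep]]; to <- genes[b[keep]]
    if (connect_causal && nrow(dataset$truth$causal) > 1L) {
      cg <- dataset$truth$causal$gene
      pairs <- utils::combn(cg, 2L)
      from <- c(from, pairs[1, ]); to <- c(to, pairs[2, ])
    }
    suppressWarnings(interaction_network(from, to))
  })
}

#' Write a synthetic dataset as the pipeline's on-disk formats
#'
#' Emits `expression.tsv`, `sensitivity.tsv`, `blind_expression.tsv`,
#' `blind_sensitivity.tsv` and a `truth.tsv` manifest into `dir`, in exactly
#' the dialects the readers consume.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_sensitivity_table(dataset$sensitivity, file.path(dir, "sensitivity.tsv"))
  write_expression_matrix(dataset$blind_expression,
                          file.path(dir, "blind_expression.tsv"))
  write_sensitivity_table(dataset$blind_sensitivity,
                          file.path(dir, "blind_sensitivity.tsv"))
  utils::write.table(dataset$truth$causal, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
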