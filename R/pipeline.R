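#' Read a plain key=value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are kept as strings; numeric fields are coerced where used.
#'
#' @param path config file path.
#' @return named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line ", bad[1], " in ", path)
  cfg <- lapply(kv, function(m) trimws(m[3]))
  names(cfg) <- vapply(kv, function(m) trimws(m[2]), "")
  pipeline_config(cfg)
}

#' Assemble a pipeline configuration
#'
#' @param ... named fields, or a single named list. Recognised fields:
#'   paths (`expression`, `sensitivity`, `blind_expression`,
#'   `blind_sensitivity`, `gmt`, `sif`, `out_dir`), `target_genes`
#'   (comma-separated), and the tunables `alpha_corr`, `top_n_relief`,
#'   `alpha_boruta`, `cv_repeats`, `cv_folds`, `holdout_size`,
#'   `tumor_threshold`, `fdr_threshold`, `exclude_lineage`, `seed`, plus the
#'   generator fields used by `simulate` (`n_train`, `n_blind`, `n_genes`,
#'   `noise_sd`, ...).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  defaults <- list(out_dir = "drugsig_out", seed = "1",
                   alpha_corr = "0.05", top_n_relief = "100",
                   alpha_boruta = "0.05", cv_repeats = "5", cv_folds = "10",
                   tumor_threshold = "60", fdr_threshold = "0.05",
                   exclude_lineage = "blood")
  cfg <- utils::modifyList(defaults, args)
  structure(cfg, class = c("pipeline_config", class(cfg)))
}

cfg_num <- function(cfg, key) as.numeric(cfg[[key]])
cfg_int <- function(cfg, key) as.integer(as.numeric(cfg[[key]]))

write_tsv <- function(df, path, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# produced by drugsig %s (stage: %s)",
                     as.character(utils::packageVersion("drugsig")), stage),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Persist a fitted signature model to a directory
#'
#' Writes `signature_importances.tsv`, the boosted-tree blob
#' (`model.xgb`), and a `model_meta.tsv` with the format version and the
#' hyperparameters needed to reload.
#'
#' @param object a fitted `drugsig`.
#' @param dir output directory.
#' @export
save_signature_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(variable_importance(object),
            file.path(dir, "signature_importances.tsv"), "derive")
  xgboost::xgb.save(object$model$fit, file.path(dir, "model.xgb"))
  meta <- data.frame(key = c("format_version", "kind", "n_trees", "max_depth",
                             "eta", "seed", "signature"),
                     value = c("1", object$model$spec$kind,
                               object$model$spec$n_trees,
                               object$model$spec$max_depth,
                               object$model$spec$eta, object$seed,
                               paste(object$signature, collapse = ",")),
                     stringsAsFactors = FALSE)
  write_tsv(meta, file.path(dir, "model_meta.tsv"), "derive")
  invisible(dir)
}

#' Reload a persisted signature model
#'
#' Returns a minimal `drugsig` handle sufficient for prediction.
#'
#' @param dir directory written by [save_signature_model()].
#' @return a `drugsig` object supporting [predict.drugsig()] and
#'   [predict_ic50()].
#' @export
load_signature_model <- function(dir) {
  meta <- read_tsv(file.path(dir, "model_meta.tsv"))
  get_meta <- function(k) meta$value[meta$key == k]
  if (get_meta("format_version") != "1")
    stop("unsupported model format version: ", get_meta("format_version"))
  signature <- strsplit(get_meta("signature"), ",", fixed = TRUE)[[1]]
  booster <- xgboost::xgb.load(file.path(dir, "model.xgb"))
  imp <- read_tsv(file.path(dir, "signature_importances.tsv"))
  spec <- model_spec("gbtree", n_trees = as.integer(get_meta("n_trees")),
                     max_depth = as.integer(get_meta("max_depth")),
                     eta = as.numeric(get_meta("eta")))
  model <- structure(list(kind = "gbtree", fit = booster,
                          features = signature, spec = spec),
                     class = "sig_regressor")
  structure(list(signature = signature, model = model,
                 importances = stats::setNames(imp$importance, imp$gene)),
            class = "drugsig")
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages as subcommands over a single
#' configuration, writing tab-separated artifacts and a run manifest into
#' `out_dir`. Subcommands: `simulate` (synthetic dataset + GMT/SIF
#' fixtures), `derive` (signature derivation; writes screen, ranking,
#' Boruta verdicts, elimination trace, signature model), `predict` (apply a
#' derived model to blind expression), `evaluate` (agreement report of
#' predictions vs actual IC50), `classify` (z-score calls + tumor-type
#' summary), `cluster` (co-clustering of selected genes; Newick export),
#' `enrich` (gene-set enrichment of the signature).
#'
#' @param config a `pipeline_config` (or path to a config file).
#' @param command one of `simulate`, `derive`, `predict`, `evaluate`,
#'   `classify`, `cluster`, `enrich`.
#' @return invisibly, a list of the stage's main results; artifacts are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config, command = c("simulate", "derive", "predict",
                                             "evaluate", "classify",
                                             "cluster", "enrich")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_int(config, "seed")
  res <- switch(command,
    simulate = stage_simulate(config, out, seed),
    derive = stage_derive(config, out, seed),
    predict = stage_predict(config, out),
    evaluate = stage_evaluate(config, out),
    classify = stage_classify(config, out),
    cluster = stage_cluster(config, out),
    enrich = stage_enrich(config, out))
  manifest <- data.frame(key = c("command", "seed",
                                 paste0("config.", names(config))),
                         value = c(command, seed,
                                   vapply(config, paste, "", collapse = ",")),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out, paste0("manifest_", command, ".tsv")),
            command)
  invisible(res)
}

stage_simulate <- function(config, out, seed) {
  grab <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  gc <- generator_config(
    n_train = grab("n_train", 52), n_blind = grab("n_blind", 37),
    n_genes = grab("n_genes", 2000),
    beta_dominant = grab("beta_dominant", 1.5),
    n_secondary = grab("n_secondary", 0),
    beta_secondary = grab("beta_secondary", 0.4),
    noise_sd = grab("noise_sd", 0.3), seed = seed)
  ds <- generate_dataset(gc)
  write_dataset(ds, out)
  write_gene_sets(generate_gene_sets(ds, seed = seed + 10L),
                  file.path(out, "gene_sets.gmt"))
  write_network(generate_network(ds, seed = seed + 11L),
                file.path(out, "network.sif"))
  ds
}

stage_derive <- function(config, out, seed) {
  expr <- read_expression_matrix(config$expression)
  sens <- read_sensitivity_table(config$sensitivity)
  gene_sets <- if (!is.null(config$gmt)) read_gene_sets(config$gmt)
  network <- if (!is.null(config$sif)) read_network(config$sif)
  targets <- if (!is.null(config$target_genes))
    strsplit(config$target_genes, ",", fixed = TRUE)[[1]]
  ctrl <- sig_control(alpha_corr = cfg_num(config, "alpha_corr"),
                      top_n_relief = cfg_int(config, "top_n_relief"),
                      alpha_boruta = cfg_num(config, "alpha_boruta"),
                      cv_repeats = cfg_int(config, "cv_repeats"),
                      cv_folds = cfg_int(config, "cv_folds"),
                      holdout_size = if (!is.null(config$holdout_size))
                        cfg_int(config, "holdout_size"),
                      exclude_lineage = if (nzchar(config$exclude_lineage))
                        config$exclude_lineage)
  fit <- derive_signature(expr, sens, gene_sets = gene_sets,
                          target_genes = targets, network = network,
                          control = ctrl, seed = seed)
  write_tsv(fit$screen, file.path(out, "correlation_screen.tsv"), "derive")
  write_tsv(fit$relief, file.path(out, "relief_ranking.tsv"), "derive")
  write_tsv(fit$boruta$decisions, file.path(out, "boruta_decisions.tsv"),
            "derive")
  if (!is.null(fit$trace))
    write_tsv(fit$trace, file.path(out, "elimination_trace.tsv"), "derive")
  save_signature_model(fit, out)
  counts <- data.frame(stage = names(fit$counts), count = unname(fit$counts))
  write_tsv(counts, file.path(out, "funnel_counts.tsv"), "derive")
  fit
}

stage_predict <- function(config, out) {
  fit <- load_signature_model(config$model_dir %||% out)
  expr <- read_expression_matrix(config$blind_expression)
  pred <- predict_ic50(fit, expr)
  write_tsv(as.data.frame(pred), file.path(out, "predictions.tsv"), "predict")
  pred
}

stage_evaluate <- function(config, out) {
  pred <- read_tsv(config$predictions %||% file.path(out, "predictions.tsv"))
  sens <- read_sensitivity_table(config$blind_sensitivity)
  m <- match(pred$sample_id, sens$sample_id)
  if (anyNA(m)) stop("predictions contain samples absent from the actual table")
  rep <- agreement_report(pred$pred_ic50_molar, sens$ic50_molar[m])
  df <- data.frame(metric = c("n", "twofold", "fourfold", "twofold_pct",
                              "fourfold_pct", "pearson_r", "pearson_p",
                              "rmse_neglog10"),
                   value = c(rep$n, rep$twofold, rep$fourfold,
                             round(100 * rep$twofold, 2),
                             round(100 * rep$fourfold, 2),
                             rep$r, rep$p, rep$rmse))
  write_tsv(df, file.path(out, "agreement_report.tsv"), "evaluate")
  rep
}

stage_classify <- function(config, out) {
  pred <- read_tsv(config$predictions %||% file.path(out, "predictions.tsv"))
  pred <- zscore_classify(pred)
  summ <- tumor_type_classify(pred, cfg_num(config, "tumor_threshold"))
  write_tsv(pred, file.path(out, "classified_predictions.tsv"), "classify")
  write_tsv(as.data.frame(summ), file.path(out, "tumor_type_summary.tsv"),
            "classify")
  list(predictions = pred, tumor_types = summ)
}

stage_cluster <- function(config, out) {
  expr <- read_expression_matrix(config$expression)
  genes <- if (!is.null(config$cluster_genes))
    strsplit(config$cluster_genes, ",", fixed = TRUE)[[1]]
    else rownames(expr$values)
  cl <- hierarchical_cluster(expr$values[genes, , drop = FALSE], "samples")
  assign <- cut_clusters(cl, 2L)
  write_tsv(data.frame(sample_id = names(assign), cluster = unname(assign)),
            file.path(out, "cluster_assignments.tsv"), "cluster")
  export_newick(cl, file.path(out, "dendrogram.nwk"))
  cl
}

stage_enrich <- function(config, out) {
  sets <- read_gene_sets(config$gmt)
  expr <- read_expression_matrix(config$expression)
  imp <- read_tsv(file.path(config$model_dir %||% out,
                            "signature_importances.tsv"))
  res <- enrichment_test(imp$gene, sets, rownames(expr$values),
                         cfg_num(config, "fdr_threshold"))
  write_tsv(as.data.frame(res), file.path(out, "enrichment.tsv"), "enrich")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
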