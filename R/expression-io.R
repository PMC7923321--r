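#' Expression matrix container
#'
#' Bundles a genes x samples matrix of log2 expression values with optional
#' per-sample annotations (tumor type and lineage). This is the container the
#' whole pipeline operates on; files in the CellMinerCDB-style tab-separated
#' dialect are read into it with [read_expression_matrix()].
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene symbols, colnames are cell-line names, both unique.
#' @param annotations optional data.frame with columns `sample_id`,
#'   `tumor_type`, `lineage`; rows matching `colnames(values)`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `annotations`.
#' @export
expression_matrix <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (!is.null(annotations)) {
    need <- c("sample_id", "tumor_type", "lineage")
    if (!all(need %in% names(annotations)))
      stop("annotations must have columns: ", paste(need, collapse = ", "))
    annotations <- annotations[match(colnames(values), annotations$sample_id), need]
    if (anyNA(annotations$sample_id))
      stop("annotations missing for some samples")
    rownames(annotations) <- NULL
  }
  structure(list(values = values, annotations = annotations),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations)) {
    tt <- table(x$annotations$lineage)
    cat("Lineages:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a genes x samples expression matrix
#'
#' Reads the tab-separated dialect used by CellMinerCDB-style exports: a
#' header row of sample names, first column the gene symbol, remaining
#' columns numeric log2 expression.
#'
#' @param path path to a tab-separated text file.
#' @param missing policy for empty/NA cells: `"error"` (default, reject the
#'   file) or `"gene_median"` (impute the within-gene median).
#' @param annotations optional annotations data.frame passed through to
#'   [expression_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, missing = c("error", "gene_median"),
                                   annotations = NULL) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": expected gene column plus >=1 sample")
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c("character", rep("numeric", length(header) - 1L)))
  gene_ids <- trimws(raw[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  rownames(vals) <- gene_ids
  colnames(vals) <- trimws(header[-1])
  if (anyNA(vals)) {
    if (missing == "error") {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing/non-numeric value at gene '%s', sample '%s' in %s",
                   rownames(vals)[idx[1]], colnames(vals)[idx[2]], path))
    }
    vals <- t(apply(vals, 1L, function(v) {
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      v
    }))
  }
  expression_matrix(vals, annotations)
}

#' Write an expression matrix in the tab-separated dialect
#'
#' Inverse of [read_expression_matrix()]; writing then re-reading restores
#' the object, and re-writing a freshly read conforming file is
#' byte-identical.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell-line IC50 sensitivity table
#'
#' Expects tab-separated columns `sample_id`, `ic50_molar`, `tumor_type`,
#' `lineage`. IC50 values are Molar; the \eqn{-\log_{10}}(M) training target
#' is derived on read.
#'
#' @param path path to the tab-separated file.
#' @return a data.frame of class `sens_table` with the four input columns
#'   plus `neglog10`.
#' @export
read_sensitivity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "ic50_molar", "tumor_type", "lineage")
  if (!all(need %in% names(df)))
    stop("sensitivity table must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- trimws(df$sample_id)
  sensitivity_table(df$sample_id, df$ic50_molar, df$tumor_type, df$lineage)
}

#' Construct a sensitivity table
#'
#' @param sample_id unique cell-line names.
#' @param ic50_molar positive IC50 values in Molar units.
#' @param tumor_type,lineage per-sample labels.
#' @return a data.frame of class `sens_table`.
#' @export
sensitivity_table <- function(sample_id, ic50_molar, tumor_type, lineage) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- !is.finite(ic50_molar) | ic50_molar <= 0
  if (any(bad))
    stop("IC50 must be positive and finite; offending sample(s): ",
         paste(sample_id[bad], collapse = ", "))
  structure(data.frame(sample_id = as.character(sample_id),
                       ic50_molar = as.numeric(ic50_molar),
                       neglog10 = -log10(as.numeric(ic50_molar)),
                       tumor_type = as.character(tumor_type),
                       lineage = as.character(lineage),
                       stringsAsFactors = FALSE),
            class = c("sens_table", "data.frame"))
}

#' Write a sensitivity table
#' @param x a `sens_table`.
#' @param path output path.
#' @export
write_sensitivity_table <- function(x, path) {
  utils::write.table(x[, c("sample_id", "ic50_molar", "tumor_type", "lineage")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict expression and sensitivity to their common samples
#'
#' Both outputs are reordered to the same sample order (order of appearance
#' in the expression matrix); counts dropped from each side are reported via
#' `message()`.
#'
#' @param expr an `expr_matrix`.
#' @param sens a `sens_table`.
#' @return a list with elements `expression` and `sensitivity`.
#' @export
align_samples <- function(expr, sens) {
  common <- intersect(colnames(expr$values), sens$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and sensitivity table")
  message(sprintf("align_samples: kept %d samples (dropped %d from expression, %d from sensitivity)",
                  length(common), ncol(expr$values) - length(common),
                  nrow(sens) - length(common)))
  vals <- expr$values[, common, drop = FALSE]
  ann <- if (!is.null(expr$annotations))
    expr$annotations[match(common, expr$annotations$sample_id), , drop = FALSE]
  list(expression = expression_matrix(vals, ann),
       sensitivity = sens[match(common, sens$sample_id), , drop = FALSE])
}

#' Drop all samples of a given lineage
#'
#' Used to remove the highly resistant blood-derived lines before signature
#' training (solid-tumor-only modelling).
#'
#' @param sens a `sens_table`.
#' @param lineage lineage label to remove (default `"blood"`).
#' @return the filtered `sens_table`.
#' @export
exclude_lineage <- function(sens, lineage = "blood") {
  hit <- sens$lineage == lineage
  if (!any(hit)) {
    warning("no samples with lineage '", lineage, "'; table unchanged")
    return(sens)
  }
  out <- sens[!hit, , drop = FALSE]
  message(sprintf("exclude_lineage: removed %d '%s' samples, %d remain",
                  sum(hit), lineage, nrow(out)))
  if (nrow(out) == 0L) warning("all samples excluded; empty sensitivity table")
  out
}

#' Convert between Molar IC50 and the -log10(M) sensitivity scale
#'
#' @param values numeric vector.
#' @param direction `"to_neglog10"` (requires strictly positive Molar input)
#'   or `"to_molar"`.
#' @return transformed numeric vector.
#' @export
transform_scale <- function(values, direction = c("to_neglog10", "to_molar")) {
  direction <- match.arg(direction)
  if (direction == "to_neglog10") {
    if (any(!is.finite(values) | values <= 0))
      stop("Molar IC50 values must be strictly positive")
    -log10(values)
  } else {
    10^(-values)
  }
}
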