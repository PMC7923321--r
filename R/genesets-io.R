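#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' members. Duplicate members within a set are collapsed with a warning.
#'
#' @param path path to a GMT file.
#' @return object of class `gene_sets`: a named list of character vectors,
#'   with the set descriptions kept in the `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicated member(s) in set '", p[1], "'; deduplicated")
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (unique names, no empty set).
#' @param descriptions optional character vector, one per set.
#' @return a `gene_sets` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(lengths(sets) == 0L)) stop("empty gene set not allowed")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_sets` object.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF interaction network
#'
#' Standard SIF: whitespace-separated `source interaction target` triples.
#' The network is treated as undirected: self-loops are dropped and
#' duplicate edges (either orientation) collapsed, each with a warning.
#'
#' @param path path to a SIF file.
#' @return object of class `interaction_network`: a data.frame with columns
#'   `from`, `to`, `type` where `from < to` lexicographically.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(interaction_network(character(), character(), character()))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("SIF line ", bad[1], " does not have exactly 3 fields in ", path)
  m <- do.call(rbind, parts)
  interaction_network(m[, 1], m[, 3], m[, 2])
}

#' Construct an undirected interaction network
#' @param from,to gene symbols at the edge endpoints.
#' @param type optional interaction-type label per edge.
#' @return an `interaction_network` data.frame.
#' @export
interaction_network <- function(from, to, type = NULL) {
  from <- as.character(from); to <- as.character(to)
  if (is.null(type)) type <- rep("pp", length(from))
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]; type <- type[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate edge(s)")
    a <- a[!dup]; b <- b[!dup]; type <- type[!dup]
  }
  structure(data.frame(from = a, to = b, type = as.character(type),
                       stringsAsFactors = FALSE),
            class = c("interaction_network", "data.frame"))
}

#' Write an interaction network as SIF
#' @param net an `interaction_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  writeLines(paste(net$from, net$type, net$to, sep = "\t"), path)
  invisible(path)
}
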