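#' Construct a functional interaction network
#'
#' An FI network is an undirected graph over gene symbols. Edges are stored
#' as a two-column data frame with optional \code{weight} (in \[0,1\]) and
#' \code{provenance} (the signed Pearson correlation the weight was derived
#' from) columns. Self-loops and duplicate edges (in either orientation) are
#' removed; gene symbols are whitespace-trimmed and matched case-sensitively.
#'
#' @param edges two-column character data frame (or matrix) of gene pairs;
#'   optional further columns \code{weight} and \code{provenance}.
#' @param nodes optional character vector of node names; defaults to the
#'   genes appearing in \code{edges}. Extra names add isolated nodes.
#' @return an object of class \code{fi_network} with elements \code{nodes}
#'   (sorted character vector) and \code{edges} (data frame with columns
#'   \code{from}, \code{to}, and optionally \code{weight}, \code{provenance};
#'   \code{from < to} lexicographically).
#' @export
fi_network <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    ed <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  } else {
    a <- trimws(as.character(edges[[1L]]))
    b <- trimws(as.character(edges[[2L]]))
    loops <- a == b
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    }
    keep <- !loops
    a <- a[keep]; b <- b[keep]
    from <- ifelse(a < b, a, b)
    to   <- ifelse(a < b, b, a)
    ed <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    extra <- intersect(c("weight", "provenance"), names(edges))
    for (cl in extra) ed[[cl]] <- as.numeric(edges[[cl]][keep])
    dup <- duplicated(paste0(ed$from, "\r", ed$to))
    ed <- ed[!dup, , drop = FALSE]
    o <- order(ed$from, ed$to)
    ed <- ed[o, , drop = FALSE]
    rownames(ed) <- NULL
  }
  nd <- sort(unique(c(ed$from, ed$to, if (!is.null(nodes)) trimws(nodes))))
  if ("weight" %in% names(ed) && nrow(ed) &&
      (any(ed$weight < 0) || any(ed$weight > 1))) {
    stop("edge weights must lie in [0, 1]")
  }
  structure(list(nodes = nd, edges = ed), class = "fi_network")
}

#' @export
print.fi_network <- function(x, ...) {
  cat(sprintf("fi_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if ("weight" %in% names(x$edges)) " (weighted)" else ""))
  invisible(x)
}

#' Read a functional interaction network from a tab-delimited edge list
#'
#' Each non-empty line must contain at least two tab-separated tokens
#' (geneA, geneB); further columns are ignored. Lines whose two genes are
#' identical are skipped with a warning; duplicate pairs in either
#' orientation collapse to a single undirected edge.
#'
#' @param path path to the edge-list file. No header is expected.
#' @return an \code{\link{fi_network}}.
#' @export
read_fi_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(fi_network(data.frame(from = character(0), to = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ntok <- lengths(parts)
  if (any(ntok < 2L)) {
    stop(sprintf("malformed edge list line %d: fewer than 2 tab-separated fields",
                 which(ntok < 2L)[1L]))
  }
  fi_network(data.frame(from = vapply(parts, `[[`, "", 1L),
                        to   = vapply(parts, `[[`, "", 2L),
                        stringsAsFactors = FALSE))
}

#' Write a network as a tab-delimited edge list
#'
#' Writes 2 columns (geneA, geneB), or 4 (plus weight and signed PCC) when
#' the network is weighted.
#'
#' @param net an \code{fi_network}.
#' @param path output file path.
#' @export
write_fi_network <- function(net, path) {
  stopifnot(inherits(net, "fi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an expression dataset with survival annotation
#'
#' Couples a genes x samples expression matrix with per-sample survival
#' follow-up. Values are log-scale intensities or z-scores; missing values
#' are disallowed (impute upstream).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param time positive per-sample survival durations (months or years,
#'   consistent within a dataset).
#' @param event per-sample indicator, 1 = event observed, 0 = censored.
#' @param covariates optional data frame of per-sample covariates
#'   (e.g. ER status), one row per sample.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(values, time, event, covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene rownames")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique sample colnames")
  if (anyNA(values)) stop("missing expression values are not allowed")
  n <- ncol(values)
  if (length(time) != n || length(event) != n)
    stop("time and event must have one entry per sample")
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per sample")
    rownames(covariates) <- colnames(values)
  }
  structure(list(values = values, time = as.numeric(time),
                 event = as.integer(event), covariates = covariates),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d events (%.0f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

#' Read an expression matrix (TSV, genes in rows)
#'
#' First column holds gene symbols; the header row holds sample identifiers.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- trimws(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_column name for the leading gene-symbol column.
#' @export
write_expression_matrix <- function(values, path, id_column = "gene") {
  df <- data.frame(values[, 0, drop = FALSE], check.names = FALSE)
  df[[id_column]] <- rownames(values)
  df <- cbind(df, as.data.frame(values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table (TSV: sample, time, event, covariates...)
#'
#' @param path path to the TSV file; must contain columns \code{sample},
#'   \code{time} and \code{event}; any further columns become covariates.
#' @return data frame with rownames set to sample ids.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  rownames(df) <- trimws(as.character(df$sample))
  df
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (name, description, genes...).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    genes <- unique(trimws(tok[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("empty gene set at GMT line %d", i))
    out[[trimws(tok[1L])]] <- genes
  }
  if (anyDuplicated(names(out))) stop("duplicate gene-set names in GMT file")
  out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to more than one gene are removed, probes with no mapping
#' are dropped, and multiple probes for the same gene are averaged
#' elementwise.
#'
#' @param probe_matrix numeric matrix, probes x samples, with probe rownames.
#' @param mapping named list: probe id -> character vector of gene symbols
#'   (possibly empty). Every probe row must have an entry.
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stop("probe_matrix must have probe rownames")
  missing <- setdiff(probes, names(mapping))
  if (length(missing))
    stop("no mapping entry for probe(s): ", paste(missing, collapse = ", "))
  ngenes <- lengths(mapping[probes])
  keep <- probes[ngenes == 1L]
  if (length(keep) == 0L) {
    out <- probe_matrix[0, , drop = FALSE]
    rownames(out) <- character(0)
    return(out)
  }
  gene <- vapply(mapping[keep], `[[`, "", 1L)
  sub <- probe_matrix[keep, , drop = FALSE]
  out <- rowsum(sub, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  out[sort(unique(gene)), , drop = FALSE]
}

#' Z-score transform expression rows
#'
#' Standardizes each gene row to mean 0 and sample (n-1) standard deviation
#' 1. Rows with zero variance cannot be standardized; they are excluded and
#' listed in the \code{dropped} attribute.
#'
#' @param values numeric matrix, genes x samples.
#' @return matrix of standardized rows, with attribute \code{dropped}: the
#'   rownames of constant rows that were removed.
#' @export
zscore_rows <- function(values) {
  values <- as.matrix(values)
  mu <- rowMeans(values)
  sdv <- apply(values, 1L, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning(sprintf("excluding %d constant row(s): %s", sum(bad),
                    paste(utils::head(rownames(values)[bad], 5L),
                          collapse = ", ")))
  }
  out <- (values[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  attr(out, "dropped") <- rownames(values)[bad]
  out
}
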