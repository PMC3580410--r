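#' Average intra-module edge weight
#'
#' Mean |PCC| over the functional-interaction edges with both endpoints in
#' the module. The average is taken over FI edges actually present, not
#' over all gene pairs: the per-edge weight is the quantity the weighted
#' network carries, and it is what the downstream size/correlation filter
#' refers to.
#'
#' @param module a \code{\link{gene_module}} or character vector of genes.
#' @param net a weighted \code{\link{fi_network}}.
#' @param all_pairs if TRUE, average over all within-module gene pairs using
#'   the signed-correlation provenance absent edges count as unavailable --
#'   only pairs connected in the network contribute. Provided for
#'   sensitivity analysis; default FALSE.
#' @return mean weight, or NA_real_ if the module has no internal edge.
#' @export
module_avg_weight <- function(module, net, all_pairs = FALSE) {
  genes <- if (inherits(module, "gene_module")) module$genes else as.character(module)
  ed <- net$edges
  if (!"weight" %in% names(ed)) stop("network is unweighted; run weight_network() first")
  inside <- ed$from %in% genes & ed$to %in% genes
  if (!any(inside)) return(NA_real_)
  mean(ed$weight[inside])
}

#' Filter MCL modules by size and average correlation
#'
#' Keeps modules with size >= \code{min_size} AND average intra-module
#' |PCC| >= \code{min_avg_weight} (both thresholds inclusive); modules with
#' no internal edge have undefined average weight and fail. Survivors are
#' renumbered 1..k by decreasing size (ties by lexicographically smallest
#' member). Defaults follow the working choice of n = 8 and p = 0.25.
#'
#' @param modules list of \code{\link{gene_module}}.
#' @param net weighted \code{\link{fi_network}} used to (re)compute average
#'   weights.
#' @param min_size minimum module size (default 8).
#' @param min_avg_weight minimum average |PCC| (default 0.25).
#' @return filtered, renumbered list of \code{gene_module}.
#' @export
filter_modules <- function(modules, net, min_size = 8L, min_avg_weight = 0.25) {
  stopifnot(min_size >= 1, min_avg_weight >= 0, min_avg_weight <= 1)
  aw <- vapply(modules, function(m) {
    if (is.na(m$avg_weight)) module_avg_weight(m, net) else m$avg_weight
  }, 0)
  keep <- vapply(modules, `[[`, 0L, "size") >= min_size &
    !is.na(aw) & aw >= min_avg_weight
  surv <- modules[keep]
  aw <- aw[keep]
  if (length(surv) == 0L) return(list())
  sizes <- vapply(surv, `[[`, 0L, "size")
  first <- vapply(surv, function(m) m$genes[1L], "")
  o <- order(-sizes, first)
  surv <- surv[o]; aw <- aw[o]
  lapply(seq_along(surv), function(k)
    gene_module(surv[[k]]$genes, rank_id = k, avg_weight = aw[k]))
}

#' Module-level expression matrix
#'
#' Collapses gene expression to one score per module and sample: the mean
#' expression of the module's member genes that are measured in the
#' dataset. Genes absent from the dataset are excluded from the mean with a
#' warning, and per-module coverage (fraction of members measured) is
#' recorded.
#'
#' @param modules list of \code{\link{gene_module}}.
#' @param expr an \code{\link{expression_dataset}} or genes x samples matrix.
#' @return object of class \code{module_matrix}: \code{values} (modules x
#'   samples, rownames \code{M<rank_id>}), \code{modules}, \code{coverage}.
#' @export
module_expression_matrix <- function(modules, expr) {
  values <- if (inherits(expr, "expression_dataset")) expr$values else as.matrix(expr)
  if (length(modules) == 0L) stop("no modules supplied")
  rows <- matrix(NA_real_, length(modules), ncol(values),
                 dimnames = list(paste0("M", vapply(modules, `[[`, 0L, "rank_id")),
                                 colnames(values)))
  coverage <- numeric(length(modules))
  missing_any <- FALSE
  for (k in seq_along(modules)) {
    m <- modules[[k]]
    measured <- intersect(m$genes, rownames(values))
    if (length(measured) == 0L)
      stop(sprintf("module %d has no measured genes", m$rank_id))
    if (length(measured) < m$size) missing_any <- TRUE
    rows[k, ] <- colMeans(values[measured, , drop = FALSE])
    coverage[k] <- length(measured) / m$size
  }
  if (missing_any)
    warning("some module genes are not measured; means use measured genes only")
  structure(list(values = rows, modules = modules, coverage = coverage),
            class = "module_matrix")
}

#' @export
print.module_matrix <- function(x, ...) {
  cat(sprintf("module_matrix: %d modules x %d samples (coverage %.2f-%.2f)\n",
              nrow(x$values), ncol(x$values), min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Write a module expression matrix as TSV
#' @param m a \code{module_matrix}.
#' @param path output path.
#' @export
write_module_matrix <- function(m, path) {
  write_expression_matrix(m$values, path, id_column = "module")
}
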