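#' Pearson correlation coefficient
#'
#' Plain Pearson correlation between two numeric vectors, used to weight
#' functional-interaction edges by co-expression.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Weight a functional interaction network by expression correlation
#'
#' Converts a static (tissue-agnostic) FI network into a disease-specific
#' weighted graph: each edge gets weight |PCC| of its two genes' expression
#' profiles, with the signed correlation kept as provenance. Edges whose
#' genes are not both measured are dropped (not zero-weighted), so the graph
#' reflects actual expression coverage. Unit mode assigns weight 1 to every
#' retained edge, giving the unweighted-clustering comparator.
#'
#' @param net an \code{\link{fi_network}}.
#' @param expr an \code{\link{expression_dataset}} (or a genes x samples
#'   matrix) supplying the correlations.
#' @param mode \code{"pcc"} (default) or \code{"unit"}.
#' @return a weighted \code{fi_network} whose edges carry \code{weight} and
#'   \code{provenance} columns; nodes are restricted to measured genes with
#'   at least the retained edges' endpoints present.
#' @export
weight_network <- function(net, expr, mode = c("pcc", "unit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "fi_network"))
  values <- if (inherits(expr, "expression_dataset")) expr$values else as.matrix(expr)
  measured <- intersect(net$nodes, rownames(values))
  if (length(measured) == 0L)
    stop("no overlap between network genes and expression genes")
  ed <- net$edges
  keep <- ed$from %in% measured & ed$to %in% measured
  ed <- ed[keep, , drop = FALSE]
  if (mode == "unit") {
    ed$weight <- rep(1, nrow(ed))
    ed$provenance <- rep(NA_real_, nrow(ed))
  } else {
    genes <- unique(c(ed$from, ed$to))
    # constant rows yield undefined correlations; their edges are dropped
    sds <- apply(values[genes, , drop = FALSE], 1L, stats::sd)
    ok <- names(sds)[sds > 0]
    bad <- nrow(ed)
    ed <- ed[ed$from %in% ok & ed$to %in% ok, , drop = FALSE]
    bad <- bad - nrow(ed)
    if (bad > 0)
      warning(sprintf("dropped %d edge(s) with undefined correlation", bad))
    if (nrow(ed)) {
      cm <- stats::cor(t(values[ok, , drop = FALSE]))
      ed$provenance <- cm[cbind(ed$from, ed$to)]
      ed$weight <- abs(ed$provenance)
      # numerical guard: |r| can exceed 1 by rounding
      ed$weight <- pmin(ed$weight, 1)
    } else {
      ed$weight <- numeric(0); ed$provenance <- numeric(0)
    }
  }
  rownames(ed) <- NULL
  fi_network(ed, nodes = unique(c(ed$from, ed$to)))
}
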