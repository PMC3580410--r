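#' MCL parameters
#'
#' Controls the Markov clustering run. The inflation coefficient is the
#' elementwise exponent applied after each expansion; larger values give
#' smaller, tighter clusters. The default of 5.0 is deliberately high so
#' that modules stay compact enough for signature work.
#'
#' @param inflation elementwise inflation exponent (> 1), default 5.0.
#' @param max_iterations iteration cap, default 200.
#' @param convergence_tol maximum elementwise change defining convergence.
#' @param prune_threshold entries below this are zeroed after inflation
#'   (columns are renormalized afterwards).
#' @param self_loop how self-loops are added before normalization:
#'   \code{"unit"} (default) gives every node a loop of weight 1, so that a
#'   weakly connected node keeps most of its transition mass on itself and
#'   is not dragged into a neighboring cluster by a single low-correlation
#'   edge; \code{"max_incident"} ties the loop to the largest incident edge
#'   weight (at least \code{min_self_loop}) instead, which merges
#'   low-weight periphery more aggressively.
#' @param min_self_loop lower bound for the max-incident loop weight.
#' @return a list of class \code{mcl_params}.
#' @export
mcl_params <- function(inflation = 5.0, max_iterations = 200L,
                       convergence_tol = 1e-6, prune_threshold = 1e-5,
                       self_loop = c("unit", "max_incident"),
                       min_self_loop = 1e-3) {
  self_loop <- match.arg(self_loop)
  stopifnot(inflation > 1, max_iterations >= 1,
            convergence_tol > 0, prune_threshold >= 0, min_self_loop > 0)
  structure(list(inflation = inflation,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 prune_threshold = prune_threshold,
                 self_loop = self_loop,
                 min_self_loop = min_self_loop),
            class = "mcl_params")
}

#' Build the column-stochastic transition matrix for MCL
#'
#' Symmetric adjacency from the weighted edges, self-loops added per the
#' loop policy (isolated nodes get a pure self-loop column), then each
#' column normalized to sum 1.
#'
#' @param net a weighted \code{\link{fi_network}}.
#' @param params an \code{\link{mcl_params}} object.
#' @return square column-stochastic matrix with node dimnames.
#' @export
build_transition_matrix <- function(net, params = mcl_params()) {
  stopifnot(inherits(net, "fi_network"))
  nodes <- sort(net$nodes)
  n <- length(nodes)
  if (n == 0L) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- net$edges
  w <- if ("weight" %in% names(ed)) ed$weight else rep(1, nrow(ed))
  if (nrow(ed)) {
    A[cbind(ed$from, ed$to)] <- w
    A[cbind(ed$to, ed$from)] <- w
  }
  loop <- if (params$self_loop == "unit") rep(1, n) else
    pmax(apply(A, 2L, max), params$min_self_loop)
  diag(A) <- loop
  sweep(A, 2L, colSums(A), "/")
}

.mcl_inflate <- function(M, inflation, prune) {
  M <- M ^ inflation
  M <- sweep(M, 2L, colSums(M), "/")
  if (prune > 0) {
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1  # fully pruned column cannot occur while diag mass persists
    M <- sweep(M, 2L, cs, "/")
  }
  M
}

#' Markov clustering of a weighted network
#'
#' Alternates expansion (matrix squaring of the column-stochastic transition
#' matrix) and inflation (elementwise power, renormalization, pruning of
#' near-zero entries) until the matrix stops changing. Clusters are read off
#' the limit matrix: rows retaining positive mass are attractors, and every
#' node joins the attractor carrying the largest mass in its column (ties go
#' to the lexicographically smallest attractor gene). The resulting modules
#' partition the node set and are numbered 1..k by decreasing size, ties
#' broken by lexicographically smallest member. Runs are deterministic.
#'
#' @param net a weighted \code{\link{fi_network}}.
#' @param params an \code{\link{mcl_params}} object.
#' @return list of \code{gene_module} objects (fields \code{genes},
#'   \code{size}, \code{avg_weight}, \code{rank_id}), with attributes
#'   \code{converged}, \code{iterations} and \code{column_sum_dev} (the
#'   largest |column sum - 1| observed after any inflation step).
#' @export
mcl_cluster <- function(net, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"))
  M <- build_transition_matrix(net, params)
  nodes <- colnames(M)
  converged <- FALSE
  max_dev <- 0
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    M_new <- .mcl_inflate(M %*% M, params$inflation, params$prune_threshold)
    max_dev <- max(max_dev, max(abs(colSums(M_new) - 1)))
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iterations; returning current clustering")

  attractors <- nodes[apply(M, 1L, max) > 0]
  sub <- M[attractors, , drop = FALSE]
  # per column: attractor with the largest mass; ties -> smallest gene name
  assign_to <- vapply(seq_along(nodes), function(j) {
    col <- sub[, j]
    m <- max(col)
    if (m <= 0) return(nodes[j])  # orphan column: own singleton
    min(attractors[col == m])
  }, "")
  groups <- split(nodes, assign_to)
  groups <- lapply(groups, sort)

  sizes <- lengths(groups)
  first <- vapply(groups, `[[`, "", 1L)
  o <- order(-sizes, first)
  groups <- groups[o]

  modules <- lapply(seq_along(groups), function(k) {
    gene_module(groups[[k]], rank_id = k,
                avg_weight = module_avg_weight(groups[[k]], net))
  })
  attr(modules, "converged") <- converged
  attr(modules, "iterations") <- iter
  attr(modules, "column_sum_dev") <- max_dev
  modules
}

#' Construct a gene module
#'
#' @param genes character vector of member gene symbols.
#' @param rank_id integer rank (1 = largest module).
#' @param avg_weight mean intra-module edge weight (|PCC|), or NA when the
#'   module has no internal FI edge.
#' @return object of class \code{gene_module}.
#' @export
gene_module <- function(genes, rank_id = NA_integer_, avg_weight = NA_real_) {
  genes <- sort(unique(as.character(genes)))
  structure(list(genes = genes, size = length(genes),
                 avg_weight = avg_weight, rank_id = as.integer(rank_id)),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("module %s: %d genes, avg |PCC| %s\n",
              ifelse(is.na(x$rank_id), "?", x$rank_id), x$size,
              ifelse(is.na(x$avg_weight), "NA", sprintf("%.3f", x$avg_weight))))
  invisible(x)
}

#' Write modules as TSV (rank_id, size, avg_weight, comma-joined genes)
#' @param modules list of \code{gene_module}.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(
    rank_id = vapply(modules, `[[`, 0L, "rank_id"),
    size = vapply(modules, `[[`, 0L, "size"),
    avg_weight = vapply(modules, `[[`, 0, "avg_weight"),
    genes = vapply(modules, function(m) paste(m$genes, collapse = ","), "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
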