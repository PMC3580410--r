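#' Supervised greedy subnetwork search (baseline)
#'
#' The classic outcome-supervised greedy expansion used as a comparator for
#' the unsupervised module pipeline. Starting from each seed gene, the
#' current module repeatedly adds the neighboring gene that most improves
#' the module score, defined as -log10 of the univariate Cox Wald P-value
#' of the module's mean expression. Candidates must lie within
#' \code{search_depth} edges of the current module and within
#' \code{max_depth} edges of the seed; expansion stops when no candidate
#' improves the score by more than \code{min_improvement}. Trajectories
#' from different seeds that end in the same gene set are deduplicated,
#' keeping the highest score.
#'
#' @param net an \code{\link{fi_network}}.
#' @param expr an \code{\link{expression_dataset}}.
#' @param search_depth candidate radius around the current module
#'   (default 1).
#' @param max_depth maximum distance of any member from its seed
#'   (default 2).
#' @param min_improvement minimum score gain to accept a candidate
#'   (default 0).
#' @param seeds optional character vector of seed genes; defaults to every
#'   gene present in both network and expression.
#' @return list of \code{\link{gene_module}} ranked by decreasing score;
#'   each carries attributes \code{score} and \code{seed} retrievable from
#'   the parallel attribute \code{scores} on the list.
#' @export
greedy_search <- function(net, expr, search_depth = 1L, max_depth = 2L,
                          min_improvement = 0, seeds = NULL) {
  stopifnot(search_depth >= 1L, search_depth <= max_depth)
  genes <- intersect(net$nodes, rownames(expr$values))
  if (length(genes) == 0L) stop("network and expression share no genes")
  if (is.null(seeds)) seeds <- genes else seeds <- intersect(seeds, genes)

  # adjacency restricted to measured genes
  ed <- net$edges[net$edges$from %in% genes & net$edges$to %in% genes, ]
  nbr <- split(c(ed$to, ed$from), c(ed$from, ed$to))
  neighbors <- function(g) {
    out <- unique(unlist(nbr[intersect(g, names(nbr))], use.names = FALSE))
    setdiff(out, g)
  }
  ring <- function(core, depth) {
    seen <- core; frontier <- core
    for (d in seq_len(depth)) {
      frontier <- setdiff(neighbors(frontier), seen)
      seen <- c(seen, frontier)
    }
    setdiff(seen, core)
  }
  module_score <- function(members) {
    score <- colMeans(expr$values[members, , drop = FALSE])
    p <- tryCatch(unname(cox_fit(score, expr$time, expr$event)$wald_p),
                  error = function(e) NA_real_)
    if (is.na(p) || p <= 0) return(NA_real_)
    -log10(p)
  }

  results <- list()
  scores <- numeric(0)
  for (seed in sort(seeds)) {
    allowed <- c(seed, ring(seed, max_depth))
    members <- seed
    sc <- module_score(members)
    if (is.na(sc)) next
    repeat {
      cand <- intersect(ring(members, search_depth), allowed)
      if (length(cand) == 0L) break
      cand_sc <- vapply(sort(cand), function(g) module_score(c(members, g)), 0)
      cand_sc <- cand_sc[!is.na(cand_sc)]
      if (length(cand_sc) == 0L) break
      best <- which.max(cand_sc)
      if (cand_sc[best] - sc <= min_improvement) break
      members <- c(members, names(cand_sc)[best])
      sc <- cand_sc[best]
    }
    key <- paste(sort(members), collapse = ",")
    if (!key %in% names(scores) || scores[[key]] < sc) {
      results[[key]] <- sort(members)
      scores[key] <- sc
    }
  }
  o <- order(-unlist(scores[names(results)]), names(results))
  mods <- lapply(seq_along(o), function(k)
    gene_module(results[[o[k]]], rank_id = k))
  attr(mods, "scores") <- unname(unlist(scores[names(results)]))[o]
  mods
}
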