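#' Permute gene identities of an expression dataset
#'
#' Randomly reassigns the gene-row labels over the same matrix rows. This
#' breaks the correspondence between genes and their network neighborhoods
#' while preserving every row's values (and therefore its relationship with
#' the survival columns) -- the null the module-discovery permutation test
#' needs. An alternative mode shuffles values within each row instead,
#' destroying the gene-survival association as well.
#'
#' @param expr an \code{\link{expression_dataset}}.
#' @param seed RNG seed; the permutation is deterministic given the seed.
#' @param mode \code{"row_label"} (default) or \code{"within_row"}.
#' @return a permuted \code{expression_dataset} with unchanged survival
#'   columns.
#' @export
permute_expression <- function(expr, seed, mode = c("row_label", "within_row")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_dataset"))
  set.seed(seed)
  v <- expr$values
  if (mode == "row_label") {
    perm <- sample(nrow(v))
    v2 <- v[perm, , drop = FALSE]
    rownames(v2) <- rownames(v)
  } else {
    v2 <- t(apply(v, 1L, sample))
    dimnames(v2) <- dimnames(v)
  }
  expression_dataset(v2, expr$time, expr$event, expr$covariates)
}

#' Null distribution of a statistic under permutation
#'
#' @param values numeric vector of null statistic values.
#' @param statistic_name label for the statistic.
#' @param seed seed used to generate the null.
#' @return object of class \code{null_distribution}.
#' @export
null_distribution <- function(values, statistic_name = "statistic", seed = NA_integer_) {
  structure(list(statistic_name = statistic_name, values = as.numeric(values),
                 n_permutations = length(values), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution of %s: %d permutations (seed %s)\n",
              x$statistic_name, x$n_permutations, x$seed))
  invisible(x)
}

#' Write a null distribution as TSV with a JSON sidecar
#' @param null a \code{null_distribution}.
#' @param path output TSV path; the sidecar gets \code{.json} appended.
#' @export
write_null_distribution <- function(null, path) {
  utils::write.table(data.frame(value = null$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(statistic = null$statistic_name,
                            n = null$n_permutations, seed = null$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Null distribution of Cox P-values for random network gene sets
#'
#' Each trial draws \code{size} distinct genes uniformly from the network
#' genes measured in the expression dataset, scores the set by its mean
#' expression, and records the univariate Cox Wald P-value of that score.
#'
#' @param net an \code{\link{fi_network}}.
#' @param size gene-set size (matched to the module under test).
#' @param expr an \code{\link{expression_dataset}}.
#' @param n_trials number of random sets.
#' @param seed RNG seed.
#' @return a \code{\link{null_distribution}} of Wald P-values.
#' @export
random_gene_set_null <- function(net, size, expr, n_trials, seed = 1L) {
  pool <- intersect(net$nodes, rownames(expr$values))
  if (size > length(pool))
    stop("size exceeds the number of measured network genes")
  set.seed(seed)
  ps <- vapply(seq_len(n_trials), function(i) {
    genes <- sample(pool, size)
    score <- colMeans(expr$values[genes, , drop = FALSE])
    fit <- cox_fit(score, expr$time, expr$event)
    unname(fit$wald_p)
  }, 0)
  null_distribution(ps, sprintf("cox_wald_p(random %d-gene set)", size), seed)
}

#' Empirical P-value against a permutation null
#'
#' The add-one estimator (r + 1) / (n + 1), where r counts null values at
#' least as extreme as the observed statistic. Never returns 0.
#'
#' @param observed observed statistic.
#' @param null a \code{\link{null_distribution}} (or numeric vector).
#' @param direction \code{"le"} if smaller values are more extreme (e.g.
#'   P-values), \code{"ge"} if larger values are.
#' @return empirical P in (0, 1\].
#' @export
empirical_pvalue <- function(observed, null, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  vals <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(vals) < 1L) stop("need at least 1 permutation")
  r <- if (direction == "le") sum(vals <= observed) else sum(vals >= observed)
  (r + 1) / (length(vals) + 1)
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= |A intersect B|) for the overlap of two gene sets drawn from a
#' common background universe (N = |background|, K = |B|, n = |A|).
#'
#' @param setA,setB character vectors of gene symbols.
#' @param background the gene universe; both sets must be contained in it.
#' @return upper-tail P-value.
#' @export
hypergeom_overlap <- function(setA, setB, background) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  if (length(setdiff(setA, background)) || length(setdiff(setB, background)))
    stop("sets must be contained in the background")
  k <- length(intersect(setA, setB))
  stats::phyper(k - 1, length(setB), length(background) - length(setB),
                length(setA), lower.tail = FALSE)
}

#' Cross-dataset P-value score
#'
#' Negative base-10 logarithm of the geometric mean of a signature's Cox
#' P-values across datasets, i.e. the mean of -log10 P. Larger is better.
#'
#' @param pvalues numeric vector of P-values in (0, 1\].
#' @param base logarithm base (default 10).
#' @return the score.
#' @export
pvalue_score <- function(pvalues, base = 10) {
  if (any(pvalues <= 0) || any(pvalues > 1))
    stop("P-values must lie in (0, 1]")
  mean(-log(pvalues, base = base))
}

#' Bonferroni correction
#' @param p P-value(s).
#' @param m number of tests.
#' @return pmin(1, p * m).
#' @export
bonferroni <- function(p, m) pmin(1, p * m)

#' Full permutation experiment for module significance
#'
#' Re-runs the module discovery chain (edge weighting, MCL, filtering,
#' per-module univariate Cox on the mean-expression score) on datasets
#' whose gene labels have been permuted, and records the smallest module
#' P-value found in each permutation. The empirical significance of an
#' observed module P-value is then \code{empirical_pvalue(p, null, "le")}:
#' the chance that a fully re-discovered null module beats it.
#'
#' @param net an \code{\link{fi_network}}.
#' @param expr an \code{\link{expression_dataset}}.
#' @param n_permutations number of label permutations (e.g. 99 for a quick
#'   check, 999+ for reporting).
#' @param seed RNG seed; permutation i uses seed + i.
#' @param mcl \code{\link{mcl_params}}.
#' @param min_size,min_avg_weight module filters.
#' @return list: \code{observed} (data frame module, size, p for the real
#'   data), \code{null} (a \code{null_distribution} of per-permutation
#'   minimum P), \code{empirical_p} (per observed module).
#' @export
permutation_experiment <- function(net, expr, n_permutations = 99L, seed = 1L,
                                   mcl = mcl_params(), min_size = 8L,
                                   min_avg_weight = 0.25) {
  run_once <- function(ds) {
    wn <- weight_network(net, ds)
    mods <- suppressWarnings(mcl_cluster(wn, mcl))
    mods <- filter_modules(mods, wn, min_size, min_avg_weight)
    if (length(mods) == 0L) return(NULL)
    mm <- module_expression_matrix(mods, ds)
    p <- vapply(seq_len(nrow(mm$values)), function(i) {
      tryCatch(unname(cox_fit(mm$values[i, ], ds$time, ds$event)$wald_p),
               error = function(e) NA_real_)
    }, 0)
    data.frame(module = vapply(mods, `[[`, 0L, "rank_id"),
               size = vapply(mods, `[[`, 0L, "size"), p = p)
  }
  observed <- run_once(expr)
  if (is.null(observed)) stop("no modules passed filters on the observed data")
  null_min <- vapply(seq_len(n_permutations), function(i) {
    tab <- run_once(permute_expression(expr, seed + i))
    if (is.null(tab) || all(is.na(tab$p))) 1 else min(tab$p, na.rm = TRUE)
  }, 0)
  null <- null_distribution(null_min, "min module cox_wald_p", seed)
  emp <- vapply(observed$p, empirical_pvalue, 0, null = null, direction = "le")
  list(observed = observed, null = null, empirical_p = emp)
}
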