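#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with a functional interaction network containing
#' planted dense modules, a single-latent-factor co-expression model per
#' module, and exponential survival whose log-hazard is linear in one
#' module's latent factor -- so the data genuinely follow the Cox model and
#' parameter recovery is well posed. With factor loading L, two genes of
#' the same module have expected correlation L^2 (0.64 at the default 0.8).
#'
#' Defaults sketch a mid-sized microarray study: 500 genes, 200 samples,
#' five planted modules of sizes 30/25/20/15/12 (the first prognostic, a
#' size comparable to the 31-gene breast signature scale this method aims
#' at), intra-module edge density 0.8 against a 0.01 background, unit
#' log-hazard per factor sd, baseline hazard 0.1 per time unit, uniform
#' censoring over 20 time units.
#'
#' @param n_genes total genes (default 500).
#' @param n_samples cohort size (default 200).
#' @param module_sizes planted module sizes (default c(30, 25, 20, 15, 12)).
#' @param intra_edge_prob edge probability within a planted module
#'   (default 0.8).
#' @param factor_loading loading of member genes on the module factor, in
#'   \[0,1\] (default 0.8).
#' @param background_edge_prob Erdos-Renyi edge probability outside modules
#'   (default 0.01).
#' @param prognostic_module index of the module driving survival
#'   (default 1).
#' @param beta log-hazard per unit of the prognostic latent factor
#'   (default 1).
#' @param baseline_hazard exponential baseline rate per time unit
#'   (default 0.1).
#' @param censor_horizon uniform censoring horizon in time units
#'   (default 20).
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 500L, n_samples = 200L,
                             module_sizes = c(30L, 25L, 20L, 15L, 12L),
                             intra_edge_prob = 0.8, factor_loading = 0.8,
                             background_edge_prob = 0.01,
                             prognostic_module = 1L, beta = 1.0,
                             baseline_hazard = 0.1, censor_horizon = 20) {
  stopifnot(n_genes >= 2, n_samples >= 2,
            all(module_sizes >= 2), sum(module_sizes) <= n_genes,
            intra_edge_prob >= 0, intra_edge_prob <= 1,
            factor_loading >= 0, factor_loading <= 1,
            background_edge_prob >= 0, background_edge_prob <= 1,
            prognostic_module >= 1, prognostic_module <= length(module_sizes),
            baseline_hazard > 0, censor_horizon > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 module_sizes = as.integer(module_sizes),
                 intra_edge_prob = intra_edge_prob,
                 factor_loading = factor_loading,
                 background_edge_prob = background_edge_prob,
                 prognostic_module = as.integer(prognostic_module),
                 beta = beta, baseline_hazard = baseline_hazard,
                 censor_horizon = censor_horizon),
            class = "synthetic_config")
}

#' Simulate a cohort with planted prognostic modules
#'
#' Network: each planted module is a dense random block
#' (\code{intra_edge_prob}); all remaining gene pairs get background edges
#' independently. Expression: member genes of module m are
#' \code{loading * f_m + sqrt(1 - loading^2) * noise} with per-sample
#' standard-normal factors f_m; other genes are pure noise. Survival:
#' exponential with rate \code{baseline_hazard * exp(beta * f_prognostic)},
#' censored at an independent Uniform(0, horizon) time.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with \code{network} (\code{fi_network}), \code{expression}
#'   (\code{expression_dataset}), and \code{truth}: module gene lists,
#'   factor matrix (samples x modules), prognostic gene set, config, seed.
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  ng <- config$n_genes; ns <- config$n_samples
  genes <- sprintf("G%04d", seq_len(ng))
  samples <- sprintf("S%03d", seq_len(ns))
  nm <- length(config$module_sizes)
  membership <- rep(0L, ng)
  at <- 0L
  modules <- vector("list", nm)
  for (m in seq_len(nm)) {
    idx <- at + seq_len(config$module_sizes[m])
    membership[idx] <- m
    modules[[m]] <- genes[idx]
    at <- at + config$module_sizes[m]
  }

  # expression: latent factor per module, shared by its members
  fac <- matrix(stats::rnorm(ns * nm), ns, nm,
                dimnames = list(samples, paste0("f", seq_len(nm))))
  L <- config$factor_loading
  values <- matrix(stats::rnorm(ng * ns), ng, ns,
                   dimnames = list(genes, samples))
  for (m in seq_len(nm)) {
    rows <- which(membership == m)
    values[rows, ] <- L * matrix(fac[, m], length(rows), ns, byrow = TRUE) +
      sqrt(1 - L^2) * values[rows, , drop = FALSE]
  }

  # survival: exponential with loglinear hazard in the prognostic factor
  f <- fac[, config$prognostic_module]
  rate <- config$baseline_hazard * exp(config$beta * f)
  t_event <- stats::rexp(ns, rate = rate)
  t_cens <- stats::runif(ns, 0, config$censor_horizon)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1e-8)

  # network: dense planted blocks + Erdos-Renyi background
  edges <- list()
  for (m in seq_len(nm)) {
    pr <- utils::combn(modules[[m]], 2L)
    keep <- stats::runif(ncol(pr)) < config$intra_edge_prob
    if (any(keep)) edges[[length(edges) + 1L]] <-
        data.frame(from = pr[1L, keep], to = pr[2L, keep])
  }
  if (config$background_edge_prob > 0) {
    pr <- utils::combn(genes, 2L)
    keep <- stats::runif(ncol(pr)) < config$background_edge_prob
    if (any(keep)) edges[[length(edges) + 1L]] <-
        data.frame(from = pr[1L, keep], to = pr[2L, keep])
  }
  net <- fi_network(do.call(rbind, edges), nodes = genes)

  expr <- expression_dataset(values, time, event)
  truth <- list(modules = modules, factors = fac,
                prognostic_genes = modules[[config$prognostic_module]],
                prognostic_module = config$prognostic_module,
                config = config, seed = seed)
  list(network = net, expression = expr, truth = truth)
}

#' Jaccard similarity of two gene sets
#' @param a,b character vectors.
#' @return |intersection| / |union|.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}
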