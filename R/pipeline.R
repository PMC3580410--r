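#' Discover a network module-based prognostic signature
#'
#' The main fitting function, wiring the full discovery chain: weight the
#' functional interaction network by expression correlation, cluster the
#' weighted graph with MCL, filter modules by size and average |PCC|, build
#' the module mean-expression matrix, pick the supervised-PC score
#' threshold by cross-validation, and fit the supervised principal
#' components survival model. A per-module univariate Cox table and the
#' per-component superpc table are part of the fit.
#'
#' @param network an \code{\link{fi_network}}.
#' @param expr an \code{\link{expression_dataset}} (training cohort).
#' @param weight_mode \code{"pcc"} or \code{"unit"} edge weighting.
#' @param mcl \code{\link{mcl_params}} for clustering.
#' @param min_size,min_avg_weight module filters (defaults 8 and 0.25).
#' @param n_components supervised PCs to fit (default 3).
#' @param folds cross-validation folds for threshold selection (default 10).
#' @param n_thresholds size of the score-quantile threshold grid.
#' @param threshold optional fixed score threshold, skipping CV.
#' @param seed seed controlling all randomness (CV fold assignment).
#' @return object of class \code{modsig}: the weighted network, filtered
#'   \code{modules}, \code{module_matrix}, \code{threshold} (with CV
#'   table), the \code{superpc} \code{model}, \code{module_cox} (per-module
#'   univariate table), and the call parameters.
#' @export
modsig <- function(network, expr, weight_mode = c("pcc", "unit"),
                   mcl = mcl_params(), min_size = 8L, min_avg_weight = 0.25,
                   n_components = 3L, folds = 10L, n_thresholds = 20L,
                   threshold = NULL, seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  stage <- function(name, fn) {
    tryCatch(fn, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  wn <- stage("weight_network", weight_network(network, expr, weight_mode))
  mods <- stage("mcl_cluster", suppressWarnings(mcl_cluster(wn, mcl)))
  mods <- stage("filter_modules",
                filter_modules(mods, wn, min_size, min_avg_weight))
  if (length(mods) == 0L) stop("no modules passed filters")
  mm <- stage("module_expression_matrix", module_expression_matrix(mods, expr))
  if (is.null(threshold)) {
    threshold <- stage("select_threshold_cv",
                       select_threshold_cv(mm, expr$time, expr$event,
                                           folds = folds,
                                           n_components = n_components,
                                           n_thresholds = n_thresholds,
                                           seed = seed))
  }
  model <- stage("fit_superpc",
                 fit_superpc(mm, expr$time, expr$event, threshold,
                             n_components))
  module_cox <- stage("module_cox", .module_cox_table(mm, expr))
  fit <- list(network = wn, modules = mods, module_matrix = mm,
              threshold = threshold, model = model, module_cox = module_cox,
              params = list(weight_mode = weight_mode, mcl = mcl,
                            min_size = min_size,
                            min_avg_weight = min_avg_weight,
                            n_components = n_components, folds = folds,
                            n_thresholds = n_thresholds, seed = seed),
              time = expr$time, event = expr$event)
  class(fit) <- "modsig"
  fit
}

.module_cox_table <- function(mm, expr) {
  do.call(rbind, lapply(seq_len(nrow(mm$values)), function(i) {
    m <- mm$modules[[i]]
    fit <- tryCatch(cox_fit(mm$values[i, ], expr$time, expr$event),
                    error = function(e) NULL)
    data.frame(module = m$rank_id, size = m$size,
               avg_weight = m$avg_weight,
               coef = if (is.null(fit)) NA_real_ else unname(fit$coefficients),
               hr = if (is.null(fit)) NA_real_ else unname(fit$hr),
               p = if (is.null(fit)) NA_real_ else unname(fit$wald_p))
  }))
}

#' @export
print.modsig <- function(x, ...) {
  cat(sprintf("modsig fit: %d filtered modules; threshold %.3f retains %d module(s)\n",
              length(x$modules), as.numeric(x$threshold),
              length(x$model$retained)))
  cat("Per-component Cox (training):\n")
  print(format(x$model$cox_table, digits = 4))
  invisible(x)
}

#' @export
summary.modsig <- function(object, ...) {
  print(object)
  cat("\nPer-module univariate Cox (training):\n")
  print(format(object$module_cox, digits = 4))
  invisible(object$module_cox)
}

#' @export
coef.modsig <- function(object, ...) coef(object$model)

#' Predict component scores or risk groups for new samples
#'
#' Builds the module matrix of \code{newdata} from the training module gene
#' lists and projects it through the fitted supervised-PC model.
#'
#' @param object a \code{modsig} fit.
#' @param newdata an \code{\link{expression_dataset}} or genes x samples
#'   matrix.
#' @param type,component passed to \code{\link{predict.superpc}}.
#' @param ... unused.
#' @export
predict.modsig <- function(object, newdata,
                           type = c("continuous", "discrete"),
                           component = 1L, ...) {
  mm <- module_expression_matrix(object$modules, newdata)
  predict(object$model, mm, type = match.arg(type), component = component)
}

#' @export
plot.modsig <- function(x, component = 1L, ...) {
  z <- x$model$training_scores[, component]
  km <- km_logrank(x$time, x$event, median_split(z))
  plot(km, main = sprintf("Training KM, PC%d median split (log-rank p = %.3g)",
                          component, km$logrank_p), ...)
  invisible(km)
}

#' Validate a fitted signature on independent cohorts
#'
#' For each validation cohort: the module matrix is rebuilt from the
#' training module gene lists (per-module gene coverage is reported;
#' modules with no measured genes are excluded with a warning), samples
#' are projected through the training model, and a univariate Cox fit per
#' component plus a per-module univariate Cox table are computed.
#' Optionally a discrete two-group prediction with Kaplan-Meier/log-rank.
#'
#' @param fit a \code{modsig} fit.
#' @param datasets named list of \code{\link{expression_dataset}}.
#' @param discrete_component if not NULL, also run discrete prediction on
#'   this component and report the log-rank test.
#' @return named list per dataset: \code{component_cox},
#'   \code{module_cox}, \code{coverage}, and optionally \code{km}.
#' @export
modsig_validate <- function(fit, datasets, discrete_component = NULL) {
  stopifnot(inherits(fit, "modsig"))
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  lapply(datasets, function(ds) {
    keep <- vapply(fit$modules, function(m)
      length(intersect(m$genes, rownames(ds$values))) > 0, TRUE)
    if (!all(keep))
      warning(sprintf("excluding %d module(s) with zero gene coverage",
                      sum(!keep)))
    mm <- suppressWarnings(module_expression_matrix(fit$modules[keep], ds))
    out <- list(
      component_cox = superpc_validate(fit$model, mm, ds$time, ds$event),
      module_cox = .module_cox_table(mm, ds),
      coverage = stats::setNames(mm$coverage, rownames(mm$values)))
    if (!is.null(discrete_component)) {
      grp <- predict(fit$model, mm, type = "discrete",
                     component = discrete_component)
      out$km <- km_logrank(ds$time, ds$event, grp)
    }
    out
  })
}
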