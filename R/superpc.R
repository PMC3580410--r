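#' Univariate Cox score statistic for one feature
#'
#' The standardized partial-likelihood score U(0)/sqrt(I(0)) under Breslow
#' tie handling, used to screen features before the supervised PCA. The
#' sign is positive when larger feature values associate with earlier
#' events.
#'
#' @param x per-sample feature values (nonconstant).
#' @param time positive survival durations.
#' @param event 0/1 indicators (>= 2 events).
#' @return signed score statistic.
#' @export
cox_univariate_score <- function(x, time, event) {
  if (sum(event) < 2L) stop("need at least 2 events")
  if (stats::sd(x) == 0) stop("constant feature: score undefined")
  d <- .breslow_derivs(0, matrix(x, ncol = 1L), time, event)
  drop(d$U) / sqrt(drop(d$I))
}

.feature_scores <- function(values, time, event) {
  apply(values, 1L, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    cox_univariate_score(x, time, event)
  })
}

# standardize columns by given centers/scales and project onto loadings
.project <- function(X, center, scale, loadings) {
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  Xs %*% loadings
}

# deterministic sign convention: largest-|loading| entry positive per column
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.stratified_folds <- function(event, folds, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (lev in c(1L, 0L)) {
    idx <- sample(which(event == lev))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Select the feature-score threshold by cross-validation
#'
#' Stratified k-fold cross-validation over a grid of candidate score
#' thresholds. For each candidate, each fold refits the screening + PCA on
#' the training portion, projects the held-out samples, and evaluates the
#' partial-likelihood-ratio statistic of Cox fits of held-out survival on
#' the first 1, 2, ..., \code{n_components} held-out component scores --
#' one CV curve per component count, as the reference supervised-PC tool
#' plots them. The selected threshold maximizes the mean CV curve for
#' \code{select_components} components (default 1: the first component is
#' the primary prognostic feature, and a joint statistic over more
#' components rewards every retained noise feature with an extra
#' chi-square degree of freedom). Ties go to the smaller threshold (more
#' features). The grid defaults to equally spaced values between the
#' smallest and largest absolute score, so that thresholds isolating the
#' strongest features are always candidates.
#'
#' @param M a \code{\link{module_matrix}} or features x samples matrix.
#' @param time,event survival outcome.
#' @param folds number of CV folds (default 10), stratified by event status.
#' @param grid optional numeric vector of candidate thresholds; defaults to
#'   \code{n_thresholds} equally spaced values over the |score| range.
#' @param n_components number of principal components (default 3).
#' @param n_thresholds grid size when \code{grid} is NULL (default 20).
#' @param select_components how many leading components the selection
#'   statistic uses (default 1).
#' @param scale_features see \code{\link{fit_superpc}}.
#' @param seed RNG seed for fold assignment.
#' @return the selected threshold, with attribute \code{cv_table} (data
#'   frame: threshold, mean features retained, one mean-CV-statistic
#'   column per component count) and attribute \code{scores} (full-data
#'   feature scores).
#' @export
select_threshold_cv <- function(M, time, event, folds = 10L, grid = NULL,
                                n_components = 3L, n_thresholds = 20L,
                                select_components = 1L,
                                scale_features = FALSE, seed = 1L) {
  values <- if (inherits(M, "module_matrix")) M$values else as.matrix(M)
  stopifnot(folds >= 2L, select_components >= 1L,
            select_components <= n_components)
  scores <- .feature_scores(values, time, event)
  if (is.null(grid)) {
    grid <- seq(min(abs(scores), na.rm = TRUE), max(abs(scores), na.rm = TRUE),
                length.out = n_thresholds)
  }
  grid <- sort(grid)
  fold <- .stratified_folds(event, folds, seed)

  cv_stat <- array(NA_real_, c(length(grid), folds, n_components))
  nfeat <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (sum(event[tr]) < 2L || sum(event[!tr]) < 1L) next
    sc_tr <- .feature_scores(values[, tr, drop = FALSE], time[tr], event[tr])
    for (g in seq_along(grid)) {
      retained <- which(!is.na(sc_tr) & abs(sc_tr) >= grid[g])
      nfeat[g, f] <- length(retained)
      if (length(retained) == 0L) next
      Xtr <- t(values[retained, tr, drop = FALSE])
      ctr <- colMeans(Xtr)
      str <- if (scale_features) apply(Xtr, 2L, stats::sd) else
        rep(1, ncol(Xtr))
      str[str == 0] <- 1
      Xs <- sweep(sweep(Xtr, 2L, ctr), 2L, str, "/")
      kmax <- min(n_components, ncol(Xs), nrow(Xs) - 1L)
      V <- .fix_signs(svd(Xs, nu = 0, nv = kmax)$v)
      Zte <- .project(t(values[retained, !tr, drop = FALSE]), ctr, str, V)
      for (k in seq_len(kmax)) {
        # small held-out folds can separate; a non-converged fit still
        # yields a usable likelihood-ratio value
        cv_stat[g, f, k] <- tryCatch(suppressWarnings({
          fit <- cox_fit(Zte[, seq_len(k), drop = FALSE],
                         time[!tr], event[!tr])
          2 * (fit$loglik - fit$loglik_null)
        }), error = function(e) NA_real_)
      }
    }
  }
  # a candidate retaining zero features in any evaluated fold is skipped
  usable <- apply(nfeat, 1L, function(v) all(is.na(v) | v > 0) && any(!is.na(v)))
  curves <- apply(cv_stat, c(1L, 3L), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  sel <- curves[, select_components]
  sel[!usable] <- NA_real_
  if (all(is.na(sel)))
    stop("no candidate threshold retained features in every fold")
  best <- max(sel, na.rm = TRUE)
  theta <- grid[min(which(!is.na(sel) & sel >= best - 1e-9))]
  tab <- data.frame(threshold = grid,
                    mean_features = rowMeans(nfeat, na.rm = TRUE))
  for (k in seq_len(n_components)) tab[[paste0("cv_stat_", k, "pc")]] <- curves[, k]
  attr(theta, "cv_table") <- tab
  attr(theta, "scores") <- scores
  theta
}

#' Fit a supervised principal components survival model
#'
#' Screens features by the absolute univariate Cox score, centers the
#' retained submatrix by its training means, extracts the top
#' right-singular vectors as component loadings, and fits a univariate Cox
#' model of survival on each component score separately. Median
#' training-score cutpoints are stored for discrete (two-group) prediction.
#'
#' The PCA is centered but, by default, not variance-scaled: when the
#' features are module mean-expression rows over z-scored genes, a tightly
#' co-expressed module has systematically larger score variance than a
#' loose one (the member-gene noise averages out only in proportion to
#' 1/size), and that variance is informative. Set
#' \code{scale_features = TRUE} for feature matrices on genuinely
#' heterogeneous scales, or z-score the matrix upstream.
#'
#' @param M a \code{\link{module_matrix}} or features x samples matrix.
#' @param time,event survival outcome.
#' @param threshold retain features with |score| >= threshold.
#' @param n_components number of principal components (default 3; capped by
#'   the retained-feature count).
#' @param scale_features divide each retained feature by its training sd
#'   before PCA (default FALSE).
#' @return object of class \code{superpc}: feature scores, threshold,
#'   retained feature ids, center/scale, loadings, training scores, per-
#'   component \code{cox_table} (coef, se, HR, CI, Wald P), cutpoints.
#' @export
fit_superpc <- function(M, time, event, threshold, n_components = 3L,
                        scale_features = FALSE) {
  values <- if (inherits(M, "module_matrix")) M$values else as.matrix(M)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  scores <- .feature_scores(values, time, event)
  retained <- rownames(values)[!is.na(scores) & abs(scores) >= threshold]
  if (length(retained) == 0L)
    stop("no features reach the score threshold ", format(threshold))
  X <- t(values[retained, , drop = FALSE])
  center <- colMeans(X)
  scale <- if (scale_features) apply(X, 2L, stats::sd) else
    stats::setNames(rep(1, ncol(X)), colnames(X))
  if (any(scale == 0)) stop("retained feature with zero variance")
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  k <- min(n_components, ncol(Xs), nrow(Xs) - 1L)
  sv <- svd(Xs, nu = 0, nv = k)
  V <- .fix_signs(sv$v[, seq_len(k), drop = FALSE])
  rownames(V) <- retained
  colnames(V) <- paste0("PC", seq_len(k))
  Z <- Xs %*% V
  cox_table <- do.call(rbind, lapply(seq_len(k), function(j) {
    fit <- cox_fit(matrix(Z[, j], dimnames = list(NULL, colnames(V)[j])),
                   time, event)
    data.frame(component = j, coef = unname(fit$coefficients),
               se = unname(fit$se), hr = unname(fit$hr),
               ci_low = fit$ci95[1L, "lower"], ci_high = fit$ci95[1L, "upper"],
               p = unname(fit$wald_p))
  }))
  model <- list(feature_ids = rownames(values),
                feature_scores = scores,
                threshold = threshold,
                retained = retained,
                center = center, scale = scale,
                loadings = V, n_components = k,
                training_scores = Z,
                cox_table = cox_table,
                cutpoints = apply(Z, 2L, stats::median),
                d = sv$d[seq_len(k)])
  class(model) <- "superpc"
  model
}

#' @export
print.superpc <- function(x, ...) {
  cat(sprintf("superpc model: %d/%d features retained at |score| >= %.3f; %d components\n",
              length(x$retained), length(x$feature_ids), x$threshold,
              x$n_components))
  print(format(x$cox_table, digits = 4))
  invisible(x)
}

#' @export
coef.superpc <- function(object, ...) {
  stats::setNames(object$cox_table$coef,
                  paste0("PC", object$cox_table$component))
}

#' @export
summary.superpc <- function(object, ...) {
  cat("Retained features:", paste(object$retained, collapse = ", "), "\n")
  print(object)
  invisible(object$cox_table)
}

#' @export
plot.superpc <- function(x, ...) {
  graphics::plot(abs(x$feature_scores), xlab = "Feature",
                 ylab = "|Cox score|", main = "Feature screening", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Predict from a supervised principal components model
#'
#' Continuous prediction standardizes new feature rows by the training
#' center/scale and projects them onto the stored loadings. Discrete
#' prediction dichotomizes one component's continuous score at the stored
#' training median; scores exactly at the cutpoint are "low".
#'
#' @param object a \code{superpc} model.
#' @param newdata a \code{\link{module_matrix}} or features x samples
#'   matrix containing every retained feature.
#' @param type \code{"continuous"} (component score matrix) or
#'   \code{"discrete"} ("low"/"high" per sample).
#' @param component component used for discrete prediction (default 1; set
#'   to 2 when the second component carries the prognostic contrast, as in
#'   some ovarian cancer cohorts).
#' @param ... unused.
#' @return samples x components score matrix, or a named character vector
#'   of groups.
#' @export
predict.superpc <- function(object, newdata,
                            type = c("continuous", "discrete"),
                            component = 1L, ...) {
  type <- match.arg(type)
  values <- if (inherits(newdata, "module_matrix")) newdata$values else as.matrix(newdata)
  missing <- setdiff(object$retained, rownames(values))
  if (length(missing))
    stop("newdata lacks retained feature(s): ", paste(missing, collapse = ", "))
  Z <- .project(t(values[object$retained, , drop = FALSE]),
                object$center, object$scale, object$loadings)
  if (type == "continuous") return(Z)
  if (component > object$n_components)
    stop("component exceeds the number of fitted components")
  cut <- object$cutpoints[component]
  stats::setNames(ifelse(Z[, component] > cut, "high", "low"), rownames(Z))
}

#' Serialize a superpc model to JSON
#' @param model a \code{superpc} model.
#' @param path output path.
#' @export
write_superpc <- function(model, path) {
  obj <- list(feature_ids = model$feature_ids,
              feature_scores = unname(model$feature_scores),
              threshold = as.numeric(model$threshold),
              retained = model$retained,
              center = as.list(model$center), scale = as.list(model$scale),
              loadings = apply(model$loadings, 2L, identity, simplify = FALSE),
              cutpoints = as.list(model$cutpoints),
              cox_table = model$cox_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-component validation of a superpc model on a new dataset
#'
#' Projects the new samples through the training model and fits a
#' univariate Cox model per component, mirroring the continuous-prediction
#' validation layout (HR, 95\% CI, Wald P per component).
#'
#' @param model a \code{superpc} model.
#' @param M_new features x samples matrix or \code{module_matrix}.
#' @param time,event survival outcome for the new samples.
#' @return data frame: component, coef, se, hr, ci_low, ci_high, p.
#' @export
superpc_validate <- function(model, M_new, time, event) {
  Z <- predict(model, M_new)
  do.call(rbind, lapply(seq_len(ncol(Z)), function(j) {
    fit <- cox_fit(Z[, j, drop = FALSE], time, event)
    data.frame(component = j, coef = unname(fit$coefficients),
               se = unname(fit$se), hr = unname(fit$hr),
               ci_low = fit$ci95[1L, "lower"], ci_high = fit$ci95[1L, "upper"],
               p = unname(fit$wald_p))
  }))
}
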