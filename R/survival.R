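# Breslow partial-likelihood machinery shared by cox_fit and the superpc
# feature screening. Event times are processed in increasing order; the risk
# set at t is {i : time_i >= t} and tied events share one denominator.

.breslow_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  o <- order(time)
  time <- time[o]; event <- event[o]; eta <- eta[o]
  n <- length(time)
  # reverse cumulative sum of exp(eta) gives risk-set denominators
  rsk <- rev(cumsum(rev(exp(eta))))
  ll <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    d <- which(event[i:j] == 1L) + i - 1L
    if (length(d)) ll <- ll + sum(eta[d]) - length(d) * log(rsk[i])
    i <- j + 1L
  }
  ll
}

.breslow_derivs <- function(beta, X, time, event) {
  X <- as.matrix(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  o <- order(time)
  time <- time[o]; event <- event[o]
  X <- X[o, , drop = FALSE]; eta <- eta[o]
  w <- exp(eta)
  n <- length(time)
  U <- numeric(p)
  I <- matrix(0, p, p)
  ll <- 0
  # suffix sums S0 = sum w, S1 = sum w*x, S2 = sum w*x x'
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- n
  # walk backwards so the risk set grows by accretion
  ends <- integer(0)
  # identify blocks of tied times from the end
  while (i >= 1L) {
    j <- i
    while (j > 1L && time[j - 1L] == time[i]) j <- j - 1L
    for (k in j:i) {
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * X[k, ]
      S2 <- S2 + w[k] * tcrossprod(X[k, ])
    }
    d <- which(event[j:i] == 1L) + j - 1L
    if (length(d)) {
      xbar <- S1 / S0
      ll <- ll + sum(eta[d]) - length(d) * log(S0)
      U <- U + colSums(X[d, , drop = FALSE]) - length(d) * xbar
      I <- I + length(d) * (S2 / S0 - tcrossprod(xbar))
    }
    i <- j - 1L
  }
  list(loglik = ll, U = U, I = I)
}

#' Cox proportional hazards fit (Breslow ties)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood, the
#' work-horse behind module scoring and validation reports. Standard errors
#' come from the inverse observed information; 95\% CIs use the normal
#' quantile 1.96 and P-values are two-sided Wald tests.
#'
#' @param X numeric matrix (samples x covariates) or vector (one covariate).
#' @param time positive survival durations.
#' @param event 0/1 event indicators (>= 2 events required).
#' @param max_iter Newton iteration cap (default 50).
#' @param tol convergence: max |change in coefficient| below this.
#' @return object of class \code{cox_fit} with \code{coefficients},
#'   \code{se}, \code{hr}, \code{ci95} (matrix, columns lower/upper),
#'   \code{wald_p}, \code{loglik}, \code{loglik_null}, \code{converged}.
#' @export
cox_fit <- function(X, time, event, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) < 2L) stop("need at least 2 events")
  if (qr(scale(X, scale = FALSE))$rank < ncol(X))
    stop("design matrix is rank deficient")
  p <- ncol(X)
  beta <- numeric(p)
  d0 <- .breslow_derivs(beta, X, time, event)
  ll0 <- d0$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- .breslow_derivs(beta, X, time, event)
    step <- tryCatch(solve(d$I, d$U), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the likelihood monotone
    h <- 1
    repeat {
      beta_new <- beta + h * step
      ll_new <- .breslow_loglik(beta_new, X, time, event)
      if (is.finite(ll_new) && ll_new >= d$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-4) { beta_new <- beta; ll_new <- d$loglik; break }
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  d <- .breslow_derivs(beta, X, time, event)
  if (!converged || max(abs(beta)) > 15)
    warning("Cox fit did not converge (possible monotone likelihood)")
  V <- tryCatch(solve(d$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(V))
  z <- beta / se
  fit <- list(coefficients = stats::setNames(beta, colnames(X)),
              se = stats::setNames(se, colnames(X)),
              hr = exp(beta),
              ci95 = cbind(lower = exp(beta - 1.96 * se),
                           upper = exp(beta + 1.96 * se)),
              wald_p = 2 * stats::pnorm(-abs(z)),
              loglik = d$loglik, loglik_null = ll0,
              score_U0 = d0$U, score_I0 = d0$I,
              converged = converged, n = n, n_events = sum(event))
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    ci_low = x$ci95[, "lower"], ci_high = x$ci95[, "upper"],
                    p = x$wald_p)
  cat(sprintf("Cox PH fit (Breslow ties), n = %d, events = %d%s\n",
              x$n, x$n_events, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(format(tab, digits = 4))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' Cox score test statistic at beta = 0
#'
#' U(0)' I(0)^{-1} U(0); for a two-group 0/1 covariate without tied event
#' times this equals the log-rank chi-square.
#'
#' @inheritParams cox_fit
#' @return chi-square statistic (df = number of covariates).
#' @export
cox_score_test <- function(X, time, event) {
  X <- as.matrix(X)
  d <- .breslow_derivs(numeric(ncol(X)), X, time, event)
  drop(crossprod(d$U, solve(d$I, d$U)))
}

#' Product-limit (Kaplan-Meier) survival curve for one sample set
#'
#' @param time positive survival durations.
#' @param event 0/1 event indicators.
#' @return data frame with columns time (distinct event times), n_risk,
#'   n_event, survival.
#' @export
km_curve <- function(time, event) {
  ut <- sort(unique(time[event == 1L]))
  if (length(ut) == 0L)
    return(data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), survival = numeric(0)))
  nr <- vapply(ut, function(t) sum(time >= t), 0)
  de <- vapply(ut, function(t) sum(time == t & event == 1L), 0)
  data.frame(time = ut, n_risk = nr, n_event = de,
             survival = cumprod(1 - de / nr))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group plus the log-rank comparison
#' (hypergeometric variance over risk sets; chi-square with k-1 degrees of
#' freedom for k groups).
#'
#' @param time positive survival durations.
#' @param event 0/1 event indicators.
#' @param group per-sample group labels (>= 2 non-empty groups).
#' @return object of class \code{km_result}: \code{curves} (data frame with
#'   group, time, n_risk, n_event, survival), \code{logrank_chi2},
#'   \code{df}, \code{logrank_p}, \code{observed}, \code{expected}.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.character(group)
  stopifnot(length(time) == length(event), length(group) == length(time))
  glev <- sort(unique(group))
  if (length(glev) < 2L) stop("need at least 2 groups")
  if (any(table(factor(group, glev)) == 0L)) stop("empty group")

  curves <- do.call(rbind, lapply(glev, function(g) {
    cu <- km_curve(time[group == g], event[group == g])
    if (nrow(cu)) cbind(group = g, cu) else
      data.frame(group = character(0), time = numeric(0), n_risk = numeric(0),
                 n_event = numeric(0), survival = numeric(0))
  }))

  # log-rank accounting over the pooled distinct event times
  ut <- sort(unique(time[event == 1L]))
  k <- length(glev)
  O <- stats::setNames(numeric(k), glev)
  E <- stats::setNames(numeric(k), glev)
  V <- matrix(0, k, k, dimnames = list(glev, glev))
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1L)
    for (gi in seq_len(k)) {
      g <- glev[gi]
      n_g <- sum(at_risk & group == g)
      O[gi] <- O[gi] + sum(time == t & event == 1L & group == g)
      E[gi] <- E[gi] + d_t * n_g / n_t
    }
    if (n_t <= 1L) next  # a lone subject contributes no variance (O = E)
    for (gi in seq_len(k)) for (gj in seq_len(k)) {
      n_i <- sum(at_risk & group == glev[gi])
      n_j <- sum(at_risk & group == glev[gj])
      V[gi, gj] <- V[gi, gj] +
        d_t * (n_i / n_t) * ((gi == gj) - n_j / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  idx <- seq_len(k - 1L)
  ome <- (O - E)[idx]
  chi2 <- if (all(abs(ome) < 1e-300)) 0 else
    drop(crossprod(ome, solve(V[idx, idx, drop = FALSE], ome)))
  res <- list(curves = curves, logrank_chi2 = chi2, df = k - 1L,
              logrank_p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
              observed = O, expected = E)
  class(res) <- "km_result"
  res
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier / log-rank: chi2 = %.4g (df = %d), p = %.4g\n",
              x$logrank_chi2, x$df, x$logrank_p))
  tab <- data.frame(observed = x$observed, expected = x$expected)
  print(format(tab, digits = 4))
  invisible(x)
}

#' @export
plot.km_result <- function(x, col = NULL, xlab = "Time", ylab = "Survival",
                           main = "Kaplan-Meier", ...) {
  glev <- unique(x$curves$group)
  if (is.null(col)) col <- seq_along(glev)
  graphics::plot(NA, xlim = c(0, max(x$curves$time, 1)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  for (i in seq_along(glev)) {
    cu <- x$curves[x$curves$group == glev[i], ]
    graphics::lines(stats::stepfun(cu$time, c(1, cu$survival)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = glev, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Write Kaplan-Meier curves as TSV (group, time, survival, at-risk)
#' @param km a \code{km_result}.
#' @param path output path.
#' @export
write_km_curves <- function(km, path) {
  utils::write.table(km$curves[, c("group", "time", "survival", "n_risk")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median split of a score vector
#'
#' Scores strictly above the median are "high", the rest (including exact
#' ties with the median) are "low" -- the higher-expression group is read as
#' the risk group.
#'
#' @param score numeric vector (>= 2 values, not all identical).
#' @return character vector of "low"/"high".
#' @export
median_split <- function(score) {
  if (length(score) < 2L) stop("need at least 2 samples")
  if (length(unique(score)) == 1L) stop("all scores identical; no split possible")
  ifelse(score > stats::median(score), "high", "low")
}
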