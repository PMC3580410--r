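test_that("cox_fit maximizes the written-out Breslow partial likelihood", {
  h <- hand_surv()
  fit <- cox_fit(h$x, h$time, h$event)
  # independent oracle: grid search over the longhand likelihood
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, breslow_loglik_longhand, 0, x = h$x, time = h$time,
               event = h$event)
  expect_lt(abs(unname(coef(fit)) - grid[which.max(ll)]), 1e-4)
  expect_lt(abs(unname(fit$loglik) - max(ll)), 1e-6)
  # definitional identities
  expect_equal(unname(fit$hr), exp(unname(coef(fit))))
  expect_equal(unname(fit$ci95[, "lower"]),
               exp(unname(coef(fit)) - 1.96 * unname(fit$se)))
})

test_that("cox_fit agrees with the survival package under ties", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 50
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tt <- round(rexp(n, exp(0.5 * X[, 1])), 1) + 0.05
  ev <- rbinom(n, 1, 0.7)
  fit <- cox_fit(X, tt, ev)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-8)
})

test_that("negating a covariate negates the coefficient and inverts the HR", {
  h <- hand_surv()
  f1 <- cox_fit(h$x, h$time, h$event)
  f2 <- cox_fit(-h$x, h$time, h$event)
  expect_equal(unname(coef(f1)), -unname(coef(f2)), tolerance = 1e-7)
  expect_equal(unname(f1$hr), 1 / unname(f2$hr), tolerance = 1e-7)
})

test_that("degenerate survival inputs are rejected", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0)), "2 events")
  expect_error(cox_fit(cbind(1:4, 2 * (1:4)), c(1, 2, 3, 4), c(1, 1, 1, 1)),
               "rank")
})

test_that("two-group Cox score test equals the log-rank chi-square", {
  set.seed(12)
  for (s in 1:3) {
    n <- 30
    g <- rbinom(n, 1, 0.5)
    tt <- rexp(n, exp(0.8 * g)) + runif(n, 0, 1e-6)  # untied
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev[g == 0]) < 1 || sum(ev[g == 1]) < 1) next
    expect_equal(cox_score_test(g, tt, ev),
                 km_logrank(tt, ev, g)$logrank_chi2, tolerance = 1e-6)
  }
})

test_that("product-limit estimator matches hand accounting", {
  cu <- km_curve(c(1, 2), c(1, 1))
  expect_equal(cu$survival, c(0.5, 0))

  # 10-subject two-group log-rank table, longhand risk-set accounting
  tt <- c(1, 2, 3, 4, 5, 1.5, 2.5, 3.5, 4.5, 6)
  ev <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  gr <- rep(c("a", "b"), each = 5)
  km <- km_logrank(tt, ev, gr)
  O <- c(a = 0, b = 0); E <- c(a = 0, b = 0); V <- 0
  for (t in sort(unique(tt[ev == 1]))) {
    risk <- tt >= t
    d <- sum(tt == t & ev == 1)
    n_t <- sum(risk); n_a <- sum(risk & gr == "a")
    O["a"] <- O["a"] + sum(tt == t & ev == 1 & gr == "a")
    O["b"] <- O["b"] + sum(tt == t & ev == 1 & gr == "b")
    E["a"] <- E["a"] + d * n_a / n_t
    E["b"] <- E["b"] + d * (n_t - n_a) / n_t
    if (n_t > 1)
      V <- V + d * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d) / (n_t - 1)
  }
  expect_equal(km$observed, O)
  expect_equal(km$expected, E)
  expect_equal(km$logrank_chi2, (O["a"] - E["a"])^2 / V, ignore_attr = TRUE)

  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  expect_equal(km$logrank_chi2, unname(ref$chisq), tolerance = 1e-10)
})

test_that("identical groups give a null log-rank test", {
  tt <- c(1, 2, 3, 4); ev <- c(1, 0, 1, 1)
  km <- km_logrank(c(tt, tt), c(ev, ev), rep(c("x", "y"), each = 4))
  expect_equal(km$logrank_chi2, 0)
  expect_equal(km$logrank_p, 1)
})

test_that("KM curves are invariant to sample ordering", {
  set.seed(13)
  tt <- rexp(20); ev <- rbinom(20, 1, 0.7); gr <- rep(c("a", "b"), 10)
  km1 <- km_logrank(tt, ev, gr)
  p <- sample(20)
  km2 <- km_logrank(tt[p], ev[p], gr[p])
  expect_equal(km1$curves, km2$curves)
  expect_equal(km1$logrank_chi2, km2$logrank_chi2)
})

test_that("median split puts boundary values in the low group", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  expect_error(median_split(c(2, 2, 2)), "identical")
})
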