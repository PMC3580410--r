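test_that("univariate Cox score matches longhand risk-set summation", {
  # 6 subjects, mixed censoring; oracle writes out U(0) and I(0) directly
  x <- c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1)
  tt <- c(3, 5, 1, 2, 4, 6)
  ev <- c(1, 0, 1, 1, 1, 0)
  U <- 0; I <- 0
  for (t in sort(unique(tt[ev == 1]))) {
    risk <- which(tt >= t)
    for (i in which(tt == t & ev == 1)) {
      U <- U + x[i] - mean(x[risk])
      I <- I + mean(x[risk]^2) - mean(x[risk])^2
    }
  }
  expect_equal(cox_univariate_score(x, tt, ev), U / sqrt(I))
})

test_that("score sign is positive when high values associate with early events", {
  # x decreases with survival time: the earliest death has the largest x
  expect_gt(cox_univariate_score(c(4, 3, 2, 1), c(1, 2, 3, 4), c(1, 1, 1, 1)), 0)
  # and the mirrored covariate flips the sign
  expect_lt(cox_univariate_score(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 1, 1, 1)), 0)
  expect_error(cox_univariate_score(rep(1, 4), c(1, 2, 3, 4), c(1, 1, 1, 1)),
               "constant")
})

test_that("single-value threshold grids are returned unchanged", {
  ds <- tiny_cohort(n_genes = 6, n_samples = 40, seed = 21)
  th <- select_threshold_cv(ds$values, ds$time, ds$event, folds = 5,
                            grid = 0.123, seed = 1)
  expect_equal(as.numeric(th), 0.123)
})

test_that("cross-validated threshold isolates a planted prognostic module", {
  cfg <- synthetic_config(n_genes = 300, n_samples = 200,
                          module_sizes = c(12L, rep(10L, 20L)))
  sim <- simulate_cohort(cfg, seed = 31)
  mods <- lapply(seq_along(sim$truth$modules), function(k)
    gene_module(sim$truth$modules[[k]], rank_id = k))
  mm <- module_expression_matrix(mods, sim$expression)
  th <- select_threshold_cv(mm, sim$expression$time, sim$expression$event,
                            seed = 31)
  model <- fit_superpc(mm, sim$expression$time, sim$expression$event, th)
  expect_true("M1" %in% model$retained)
  expect_gt(abs(cor(model$training_scores[, 1], sim$truth$factors[, 1])), 0.9)
})

test_that("a one-feature model reduces to the standardized feature", {
  ds <- tiny_cohort(n_genes = 1, n_samples = 30, seed = 22)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = -Inf,
                       scale_features = TRUE)
  expect_equal(abs(unname(model$loadings[1, 1])), 1)
  z <- model$training_scores[, 1]
  expect_equal(unname(z), unname(scale(ds$values[1, ])[, 1] *
                                   sign(model$loadings[1, 1])))
})

test_that("retaining everything reproduces plain PCA up to sign", {
  ds <- tiny_cohort(n_genes = 8, n_samples = 40, seed = 23)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = 0,
                       n_components = 3)
  ref <- prcomp(t(ds$values), center = TRUE, scale. = FALSE)
  for (j in 1:3)
    expect_equal(abs(unname(model$loadings[, j])),
                 abs(unname(ref$rotation[, j])), tolerance = 1e-8)
})

test_that("prediction is a training-referenced linear projection", {
  ds <- tiny_cohort(n_genes = 6, n_samples = 30, seed = 24)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = 0,
                       n_components = 2)
  # projecting the training data reproduces the stored scores
  expect_equal(predict(model, ds$values), model$training_scores)
  # the feature-mean sample scores 0 on every component
  mu <- matrix(model$center, ncol = 1,
               dimnames = list(model$retained, "m"))
  expect_equal(unname(predict(model, mu)[1, ]), rep(0, 2))
  # +1 training-sd on one retained feature moves scores by loading * sd
  f <- model$retained[2]
  shifted <- mu; shifted[f, 1] <- shifted[f, 1] + sd(ds$values[f, ])
  expect_equal(unname(predict(model, shifted)[1, ] - predict(model, mu)[1, ]),
               unname(model$loadings[f, ] * sd(ds$values[f, ]) /
                        model$scale[f]))
  # missing retained features are reported by name
  expect_error(predict(model, ds$values[-2, ]), model$retained[2])
})

test_that("component scores are invariant to sample ordering", {
  ds <- tiny_cohort(n_genes = 6, n_samples = 30, seed = 25)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = 0)
  p <- sample(30)
  expect_equal(predict(model, ds$values[, p]),
               model$training_scores[p, ])
})

test_that("discrete prediction splits at the training median, ties low", {
  ds <- tiny_cohort(n_genes = 6, n_samples = 30, seed = 26)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = 0,
                       n_components = 2)
  grp <- predict(model, ds$values, type = "discrete")
  expect_equal(sort(unname(table(grp))), c(15L, 15L), ignore_attr = TRUE)
  # odd n: the median is itself a training score and must fall in "low"
  ds31 <- tiny_cohort(n_genes = 6, n_samples = 31, seed = 29)
  m31 <- fit_superpc(ds31$values, ds31$time, ds31$event, threshold = 0,
                     n_components = 2)
  g31 <- predict(m31, ds31$values, type = "discrete")
  at_median <- which(m31$training_scores[, 1] == m31$cutpoints[1])
  expect_length(at_median, 1)
  expect_equal(unname(g31[at_median]), "low")
  expect_equal(as.vector(table(g31)[c("high", "low")]), c(15L, 16L))
  # requesting the 2nd component drives the grouping by PC2
  g2 <- predict(model, ds$values, type = "discrete", component = 2)
  expect_equal(unname(g2),
               unname(ifelse(model$training_scores[, 2] > model$cutpoints[2],
                             "high", "low")))
})

test_that("per-component summaries expose HR and Wald 95% intervals", {
  ds <- tiny_cohort(n_genes = 6, n_samples = 40, seed = 27)
  model <- fit_superpc(ds$values, ds$time, ds$event, threshold = 0)
  tab <- model$cox_table
  expect_equal(tab$hr, exp(tab$coef))
  expect_equal(tab$ci_low, exp(tab$coef - 1.96 * tab$se))
  expect_equal(tab$ci_high, exp(tab$coef + 1.96 * tab$se))
  expect_equal(nrow(tab), 3)  # three per-component rows by default
})
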