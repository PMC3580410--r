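test_that("gene-label permutation preserves rows and survival columns", {
  ds <- tiny_cohort(n_genes = 10, n_samples = 15, seed = 41)
  p1 <- permute_expression(ds, seed = 7)
  p2 <- permute_expression(ds, seed = 7)
  expect_equal(p1$values, p2$values)                       # deterministic
  expect_equal(p1$time, ds$time)
  expect_equal(p1$event, ds$event)
  # the multiset of rows is conserved, only labels move
  key <- function(m) sort(unname(apply(m, 1, paste, collapse = ",")))
  expect_equal(key(p1$values), key(ds$values))
  expect_equal(rownames(p1$values), rownames(ds$values))
  # within-row mode keeps each row's multiset instead
  w <- permute_expression(ds, seed = 8, mode = "within_row")
  expect_equal(t(apply(w$values, 1, sort)), t(apply(ds$values, 1, sort)))
})

test_that("empirical P-values follow the add-one estimator", {
  expect_equal(empirical_pvalue(0.5, rep(1, 1000), "le"), 1 / 1001)
  expect_equal(empirical_pvalue(3, rep(3, 5), "le"), 1)
  expect_equal(empirical_pvalue(0.2, c(rep(0.1, 49), rep(0.9, 50)), "le"), 0.5)
  # adding an extreme null value can only increase the empirical P
  null <- runif(50)
  p0 <- empirical_pvalue(0.1, null, "le")
  expect_gte(empirical_pvalue(0.1, c(null, 0.01), "le"), p0)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  bg <- LETTERS[1:10]
  A <- LETTERS[1:5]; B <- LETTERS[1:5]
  expect_equal(hypergeom_overlap(A, B, bg), 1 / choose(10, 5))
  expect_equal(hypergeom_overlap(LETTERS[1:3], LETTERS[4:6], bg), 1)
  expect_equal(hypergeom_overlap(bg, bg, bg), 1)
  expect_error(hypergeom_overlap(c("A", "Z"), B, bg), "background")

  # enumeration oracle over all C(N, n) draws for N <= 12
  for (case in list(c(N = 9, K = 4, n = 3), c(N = 12, K = 5, n = 6))) {
    bg <- paste0("x", seq_len(case["N"]))
    B <- bg[seq_len(case["K"])]
    draws <- utils::combn(case["N"], case["n"])
    for (k_obs in 1:min(case["K"], case["n"])) {
      tail_count <- sum(apply(draws, 2, function(d)
        length(intersect(bg[d], B)) >= k_obs))
      A <- c(bg[seq_len(k_obs)],
             bg[setdiff(seq_len(case["N"]), seq_len(case["K"]))][
               seq_len(case["n"] - k_obs)])
      expect_equal(hypergeom_overlap(A, B, bg), tail_count / ncol(draws))
    }
  }
})

test_that("the P-value score is the mean negative log10 P", {
  expect_equal(pvalue_score(c(1e-2, 1e-4)), 3.0)
  expect_equal(pvalue_score(c(0.05, 0.05, 0.05)), -log10(0.05))
  expect_error(pvalue_score(c(0.5, 0)), "0, 1")
  # permutation invariance and monotonicity
  p <- c(0.2, 0.01, 0.6)
  expect_equal(pvalue_score(p), pvalue_score(rev(p)))
  expect_gt(pvalue_score(c(0.1, 0.01, 0.6)), pvalue_score(p))
})

test_that("bonferroni multiplies and caps at 1", {
  expect_equal(bonferroni(0.002, 27), 0.054)
  expect_equal(bonferroni(0.2, 27), 1)
})

test_that("random gene-set nulls are reproducible and size-checked", {
  ds <- tiny_cohort(n_genes = 20, n_samples = 40, seed = 42)
  net <- fi_network(data.frame(from = rownames(ds$values)[1:19],
                               to = rownames(ds$values)[2:20]))
  n1 <- random_gene_set_null(net, 5, ds, n_trials = 20, seed = 3)
  n2 <- random_gene_set_null(net, 5, ds, n_trials = 20, seed = 3)
  expect_equal(n1$values, n2$values)
  expect_equal(n1$n_permutations, 20)
  expect_error(random_gene_set_null(net, 100, ds, 5), "size exceeds")
  expect_equal(random_gene_set_null(net, 5, ds, 0)$values, numeric(0))
})

test_that("null distributions round-trip through TSV + JSON sidecar", {
  nd <- null_distribution(c(0.1, 0.5, 0.9), "demo_stat", seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_distribution(nd, f)
  expect_equal(utils::read.delim(f)$value, nd$values)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$n, 3)
  expect_equal(side$statistic, "demo_stat")
})
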