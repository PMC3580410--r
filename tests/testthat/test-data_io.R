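test_that("edge lists deduplicate unordered pairs and drop self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB", "B\tA", "A\tC"), f)
  net <- read_fi_network(f)
  expect_length(net$nodes, 3)
  expect_equal(nrow(net$edges), 2)

  writeLines(character(0), f)
  empty <- read_fi_network(f)
  expect_length(empty$nodes, 0)
  expect_equal(nrow(empty$edges), 0)

  writeLines(c("A\tA", "A\tB"), f)
  expect_warning(net2 <- read_fi_network(f), "self-loop")
  expect_equal(nrow(net2$edges), 1)

  writeLines(c("A\tB", "loner"), f)
  expect_error(read_fi_network(f), "line 2")
})

test_that("network and expression round-trip through their TSV formats", {
  net <- fi_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                               weight = c(0.5, 0.25),
                               provenance = c(-0.5, 0.25)))
  f <- withr::local_tempfile()
  write_fi_network(net, f)
  back <- read_fi_network(f)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[, c("from", "to")], net$edges[, c("from", "to")])

  ds <- tiny_cohort(n_genes = 5, n_samples = 4, seed = 2)
  write_expression_matrix(ds$values, f)
  expect_equal(read_expression_matrix(f), ds$values)
})

test_that("gene sets round-trip through GMT", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("D", "E"))
  f <- withr::local_tempfile()
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})

test_that("probe collapsing averages same-gene probes and drops ambiguous ones", {
  pm <- matrix(c(1, 3, 3, 5, 9, 9, 7, 7), 4, 2, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3", "p4"), c("s1", "s2")))
  mapping <- list(p1 = "G1", p2 = "G1", p3 = c("G1", "G2"), p4 = character(0))
  out <- collapse_probes(pm, mapping)
  expect_equal(rownames(out), "G1")
  expect_equal(unname(out["G1", ]), c(2, 4))

  expect_error(collapse_probes(pm, mapping[1:3]), "p4")
})

test_that("z-scoring standardizes rows and excludes constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
  # idempotent on already standardized rows
  expect_equal(zscore_rows(z), z, ignore_attr = TRUE, tolerance = 1e-12)

  m2 <- rbind(m, flat = c(5, 5, 5))
  expect_warning(z2 <- zscore_rows(m2), "constant")
  expect_equal(attr(z2, "dropped"), "flat")
  expect_equal(rownames(z2), c("a", "b"))
})

test_that("expression datasets validate their survival annotation", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(expression_dataset(v, time = c(1, 2, 0), event = c(1, 0, 1)),
               "positive")
  expect_error(expression_dataset(v, time = c(1, 2, 3), event = c(1, 2, 0)),
               "0 or 1")
  v[1, 1] <- NA
  expect_error(expression_dataset(v, time = c(1, 2, 3), event = c(1, 0, 1)),
               "missing")
})
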