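test_that("average module weight is the mean over present intra-module edges", {
  net <- fi_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                               weight = c(0.3, 0.5, 0.9),
                               provenance = c(0.3, 0.5, 0.9)))
  expect_equal(module_avg_weight(c("A", "B", "C"), net), 0.4)
  expect_equal(module_avg_weight(c("A", "B"), net), 0.3)
  # no internal edges -> undefined
  expect_true(is.na(module_avg_weight(c("A", "D"), net)))
})

test_that("module filters are inclusive and survivors are renumbered by size", {
  genes <- sprintf("g%03d", 1:120)
  mk <- function(g, w) gene_module(g, avg_weight = w)
  net <- fi_network(data.frame(from = "g001", to = "g002", weight = 0.5,
                               provenance = 0.5))
  mods <- list(mk(genes[1:3], 0.9),        # too small
               mk(genes[4:11], 0.25),      # size 8, boundary pcc: kept
               mk(genes[12:81], 0.30),     # size 70: kept
               mk(genes[82:112], 0.24),    # pcc below threshold
               mk(genes[113:119], 0.9))    # size 7
  kept <- filter_modules(mods, net)
  expect_equal(sapply(kept, `[[`, "size"), c(70, 8))
  expect_equal(sapply(kept, `[[`, "rank_id"), c(1, 2))
  expect_equal(sapply(kept, `[[`, "avg_weight"), c(0.30, 0.25))

  # survivors of sizes 9 and 31 get ranks 2 and 1
  kept2 <- filter_modules(list(mk(genes[1:9], 0.5), mk(genes[10:40], 0.5)), net)
  expect_equal(sapply(kept2, `[[`, "size"), c(31, 9))

  expect_equal(filter_modules(list(), net), list())
  # idempotence
  expect_equal(filter_modules(kept, net), kept)
})

test_that("module expression rows are means over measured member genes", {
  v <- rbind(g1 = c(1, 3), g2 = c(3, 5), g3 = c(10, 20))
  colnames(v) <- c("s1", "s2")
  m <- module_expression_matrix(list(gene_module(c("g1", "g2"), rank_id = 1)), v)
  expect_equal(unname(m$values[1, ]), c(2, 4))
  expect_equal(m$coverage, 1)

  # single-gene module equals the gene row
  m1 <- module_expression_matrix(list(gene_module("g3", rank_id = 1)), v)
  expect_equal(unname(m1$values[1, ]), unname(v["g3", ]))

  # unmeasured genes are excluded from the mean, coverage recorded
  mod <- gene_module(c("g1", "g2", "g3", "g9"), rank_id = 2)
  expect_warning(m2 <- module_expression_matrix(list(mod), v), "not measured")
  expect_equal(unname(m2$values[1, ]), unname(colMeans(v)))
  expect_equal(m2$coverage, 0.75)

  expect_error(
    suppressWarnings(
      module_expression_matrix(list(gene_module("absent", rank_id = 1)), v)),
    "no measured genes")
})

test_that("module matrix commutes with sample reordering", {
  ds <- tiny_cohort(n_genes = 8, n_samples = 12, seed = 6)
  mods <- list(gene_module(rownames(ds$values)[1:4], rank_id = 1),
               gene_module(rownames(ds$values)[5:8], rank_id = 2))
  m <- module_expression_matrix(mods, ds$values)
  perm <- sample(ncol(ds$values))
  mp <- module_expression_matrix(mods, ds$values[, perm])
  expect_equal(mp$values, m$values[, perm])
})
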