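test_that("generators are pure functions of their config (seed determinism)", {
  cfg <- sim_config(seed = 5, n_genes = 200, n_de = 30, n_query_mapped = 25,
                    n_connectable = 15, n_anchors = 6)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(unclass(e1$matrix), unclass(e2$matrix))
  expect_identical(e1$planted, e2$planted)

  d1 <- simulate_database(cfg, e1$planted$gene_id)
  d2 <- simulate_database(cfg, e2$planted$gene_id)
  expect_identical(d1$db$edges, d2$db$edges)
  expect_identical(d1$target, d2$target)

  a1 <- simulate_annotations(cfg, d1$connectable[1:6])
  a2 <- simulate_annotations(cfg, d2$connectable[1:6])
  expect_identical(a1$collection$terms, a2$collection$terms)

  # a different seed changes the data
  e3 <- simulate_expression(sim_config(seed = 6, n_genes = 200, n_de = 30,
                                       n_query_mapped = 25, n_connectable = 15))
  expect_false(identical(unclass(e1$matrix), unclass(e3$matrix)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_expression(sim_config(seed = 1, n_genes = 50, n_de = 5,
                                           n_query_mapped = 4,
                                           n_connectable = 3)))
  expect_identical(runif(1), before)
})

test_that("zero-noise expression reproduces the planted effects exactly", {
  cfg <- sim_config(seed = 2, n_genes = 100, n_de = 10, noise_sd = 0,
                    n_query_mapped = 8, n_connectable = 5)
  expr <- simulate_expression(cfg)
  g <- expr$groups
  x <- unclass(expr$matrix)
  emp <- rowMeans(x[, g$sample_id[g$group == "case"]]) -
    rowMeans(x[, g$sample_id[g$group == "control"]])
  expect_equal(unname(emp[expr$planted$gene_id]), expr$planted$log2fc,
               tolerance = 1e-12)
  expect_true(all(abs(emp[setdiff(rownames(x), expr$planted$gene_id)]) < 1e-12))
  expect_true(all(abs(expr$planted$log2fc) > 1))  # planted FC always > 2
})

test_that("planted database topology: target dominance, mapping and isolation", {
  cfg <- sim_config(seed = 4, n_genes = 500)
  expr <- simulate_expression(cfg)
  sim <- simulate_database(cfg, expr$planted$gene_id)
  expect_identical(length(sim$mapped), 69L)
  expect_identical(length(sim$connectable), 39L)
  expect_identical(length(sim$isolated), 30L)

  # target has strictly the largest database degree among query genes
  deg_of <- function(gene) sum(sim$db$edges$node1 == gene) +
    sum(sim$db$edges$node2 == gene)
  dtgt <- deg_of(sim$target)
  others <- vapply(setdiff(sim$mapped, sim$target), deg_of, 0L)
  expect_gt(dtgt, max(others))

  # the query network mirrors the narrative: 69/81 mapped, isolated queries
  # have no edges after augmentation and are shed by the main component
  net <- induce_query_network(sim$db, expr$planted$gene_id)
  expect_identical(net$provenance$n_query_mapped, 69L)
  expect_identical(length(net$provenance$unrecognized), 12L)
  aug <- add_first_neighbors(sim$db, net, m = 20)
  deg_aug <- igraph::degree(aug$graph)
  expect_true(all(deg_aug[sim$isolated] == 0))
  main <- main_component(aug)
  expect_identical(main$provenance$n_main_component, 59L)
  expect_identical(main$provenance$n_query_isolated_removed, 30L)
  expect_identical(main$provenance$n_neighbors_added, 20L)
  expect_setequal(
    igraph::V(main$graph)$name[igraph::V(main$graph)$role == "neighbor"],
    sim$anchors)
})

test_that("planted annotation blocks separate within- from cross-block kappa", {
  cfg <- sim_config(seed = 8)
  ann <- simulate_annotations(cfg, sprintf("CRUCIAL%d", 1:9))
  coll <- ann$collection
  ids <- names(ann$blocks)
  within <- c(); across <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      kap <- kappa_score(coll$terms[[ids[i]]], coll$terms[[ids[j]]],
                         coll$universe)
      if (ann$blocks[ids[i]] == ann$blocks[ids[j]]) within <- c(within, kap)
      else across <- c(across, kap)
    }
  }
  expect_gt(min(within), max(across))
  expect_gt(min(within), 0.4)
  expect_lt(max(across), 0.4)
})

test_that("the reference fixture has the reported shape", {
  fx <- reference_centrality_fixture()
  expect_identical(nrow(fx$centrality), 39L)
  expect_identical(length(fx$crucial), 7L)
  expect_identical(attr(fx$centrality, "component_size"), 59L)
  expect_setequal(union(fx$hubs, fx$bottlenecks), fx$crucial)
  expect_identical(intersect(fx$hubs, fx$bottlenecks), "GATA3")
})

test_that("simulate_study writes a complete, pipeline-ready file set", {
  outdir <- file.path(tempdir(), "study1")
  cfg <- sim_config(seed = 12, n_genes = 400)
  paths <- simulate_study(cfg, outdir)
  for (f in c("expression", "sample_map", "database", "gmt", "truth")) {
    expect_true(file.exists(paths[[f]]))
  }
  m <- read_expression(paths$expression)
  expect_identical(dim(m), c(400L, 40L))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_identical(length(truth$mapped), 69L)
})
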