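write_db_fixture <- function(lines) {
  path <- tempfile("db", fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("database loading deduplicates, thresholds, and validates", {
  db <- load_database(write_db_fixture(c("A\tB\t900", "B\tA\t700")), 400)
  expect_identical(nrow(db$edges), 1L)
  expect_identical(db$edges$score, 900L)

  db2 <- load_database(write_db_fixture(c("A\tB\t399", "A\tC\t400")), 400)
  expect_identical(db2$edges$node2, "C")

  expect_warning(db3 <- load_database(write_db_fixture(character(0)), 400),
                 "empty")
  expect_identical(nrow(db3$edges), 0L)

  expect_error(load_database(write_db_fixture(c("A\tB\t500", "A\tB")), 400),
               "line 2")
  expect_error(load_database(write_db_fixture("A\tB\t1500"), 400),
               "\\[0, 1000\\]")

  # header line and space separation are tolerated
  db4 <- load_database(write_db_fixture(c("protein1 protein2 combined_score",
                                          "A B 800")), 400)
  expect_identical(db4$edges$score, 800L)

  # self-loops never survive
  db5 <- load_database(write_db_fixture(c("A\tA\t999", "A\tB\t800")), 400)
  expect_identical(nrow(db5$edges), 1L)
})

test_that("query induction maps genes and reports the unrecognized", {
  db <- load_database(write_db_fixture(c("A\tB\t500", "C\tD\t500")), 400)
  # C is in the universe but has no edge among the query: kept, isolated
  net <- induce_query_network(db, c("A", "B", "C"))
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_identical(net$provenance$n_query_mapped, 3L)
  expect_identical(unname(igraph::degree(net$graph)["C"]), 0)

  # E is absent from the database universe entirely: reported unrecognized
  net1 <- induce_query_network(db, c("A", "B", "E"))
  expect_identical(net1$provenance$n_query_mapped, 2L)
  expect_identical(net1$provenance$unrecognized, "E")

  net2 <- induce_query_network(db, c("X", "Y"))
  expect_identical(net2$provenance$n_query_mapped, 0L)
  expect_setequal(net2$provenance$unrecognized, c("X", "Y"))
})

test_that("first-neighbor addition ranks by connections, confidence, id", {
  db <- load_database(write_db_fixture(c(
    "Q1\tX\t500", "Q2\tX\t500", "Q3\tX\t500",  # X touches 3 query genes
    "Q1\tY\t999",                              # Y touches 1
    "X\tZ\t900")), 400)
  net <- induce_query_network(db, c("Q1", "Q2", "Q3"))
  aug <- add_first_neighbors(db, net, m = 1)
  roles <- igraph::V(aug$graph)$role
  expect_identical(igraph::V(aug$graph)$name[roles == "neighbor"], "X")

  # m = 0 is the identity
  same <- add_first_neighbors(db, net, m = 0)
  expect_equal(igraph::vcount(same$graph), igraph::vcount(net$graph))

  # tie on connections and summed confidence -> smaller id
  db2 <- load_database(write_db_fixture(c("Q1\tN2\t700", "Q1\tN1\t700")), 400)
  net2 <- induce_query_network(db2, "Q1")
  aug2 <- add_first_neighbors(db2, net2, m = 1)
  expect_identical(
    igraph::V(aug2$graph)$name[igraph::V(aug2$graph)$role == "neighbor"], "N1")

  # shortfall: fewer candidates than requested
  expect_warning(aug3 <- add_first_neighbors(db2, net2, m = 5), "only 2")
  expect_identical(aug3$provenance$n_neighbors_added, 2L)
})

test_that("neighbor addition never removes nodes or edges and neighbors touch queries", {
  cfg <- sim_config(seed = 3, n_genes = 300, n_de = 81)
  expr <- simulate_expression(cfg)
  sim <- simulate_database(cfg, expr$planted$gene_id)
  net <- induce_query_network(sim$db, expr$planted$gene_id)
  aug <- add_first_neighbors(sim$db, net, m = 20)
  expect_true(all(igraph::V(net$graph)$name %in% igraph::V(aug$graph)$name))
  expect_gte(igraph::ecount(aug$graph), igraph::ecount(net$graph))
  # every added neighbor is adjacent to >= 1 query node in the database
  nbrs <- igraph::V(aug$graph)$name[igraph::V(aug$graph)$role == "neighbor"]
  q <- igraph::V(net$graph)$name
  for (nb in nbrs) {
    touches <- sim$db$edges$node1 == nb & sim$db$edges$node2 %in% q |
      sim$db$edges$node2 == nb & sim$db$edges$node1 %in% q
    expect_true(any(touches))
  }
})

test_that("main component keeps the largest component and reports exclusions", {
  gr <- graph_from_edges("A", "B", "B", "C", "C", "D", "D", "E",
                         "X", "Y", "Y", "Z")
  main <- main_component(as_network(gr))
  expect_identical(sort(igraph::V(main$graph)$name), c("A", "B", "C", "D", "E"))
  expect_setequal(main$provenance$excluded$node_id, c("X", "Y", "Z"))
  expect_identical(main$provenance$n_main_component, 5L)

  # tie on size -> component containing the lexicographically smallest id
  tie <- graph_from_edges("M", "N", "A", "Z")
  kept <- main_component(as_network(tie))
  expect_setequal(igraph::V(kept$graph)$name, c("A", "Z"))

  full <- graph_from_edges("A", "B", "B", "C")
  expect_identical(nrow(main_component(as_network(full))$provenance$excluded), 0L)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_error(main_component(as_network(empty)), "empty")
})

test_that("network construction is invariant under input row order", {
  rows <- c("A\tB\t500", "B\tC\t600", "C\tD\t700", "A\tD\t800", "D\tE\t900")
  db1 <- load_database(write_db_fixture(rows), 400)
  db2 <- load_database(write_db_fixture(rev(rows)), 400)
  expect_identical(db1$edges, db2$edges)
  n1 <- induce_query_network(db1, c("A", "B", "C", "D", "E"))
  n2 <- induce_query_network(db2, c("E", "D", "C", "B", "A"))
  expect_equal(igraph::ecount(n1$graph), igraph::ecount(n2$graph))
  expect_identical(sort(igraph::V(n1$graph)$name),
                   sort(igraph::V(n2$graph)$name))
})

test_that("scale-free diagnostic follows its rule on constructed graphs", {
  star <- igraph::make_star(10, mode = "undirected")
  out <- scale_free_check(star)
  expect_equal(out$isolated_fraction, 0)
  expect_equal(out$slope, -1, tolerance = 1e-9)   # two degree classes, exact
  expect_equal(out$r_squared, 1)
  expect_identical(out$verdict, "scale-free-like")

  sparse <- igraph::make_empty_graph(50, directed = FALSE) +
    igraph::make_full_graph(3)
  out2 <- scale_free_check(sparse)
  expect_equal(out2$isolated_fraction, 50 / 53, tolerance = 1e-12)
  expect_identical(out2$verdict, "not scale-free")
  expect_identical(out2$note, "weak interactions")

  alliso <- igraph::make_empty_graph(5, directed = FALSE)
  expect_identical(scale_free_check(alliso)$verdict, "not scale-free")
})

test_that("preferential-attachment graphs are usually called scale-free-like", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    gr <- igraph::sample_pa(500, power = 1, m = 2, directed = FALSE)
    if (scale_free_check(gr)$verdict == "scale-free-like") hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("SIF and GraphML exports carry the network", {
  gr <- graph_from_edges("A", "B", "B", "C")
  net <- as_network(gr)
  sif <- tempfile(fileext = ".sif")
  write_sif(net, sif)
  expect_identical(readLines(sif), c("A\tpp\tB", "B\tpp\tC"))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_setequal(igraph::vertex_attr_names(back),
                  c("name", "role", "degree", "betweenness", "id"))
})
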