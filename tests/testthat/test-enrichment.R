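toy_collection <- function() {
  universe <- sprintf("g%02d", 1:20)
  annotation_collection(list(
    T1 = universe[1:5],     # the term of the worked example
    T2 = universe,          # covers the whole universe
    T3 = universe[6:9]))
}

test_that("hypergeometric p matches the closed form and exhaustive enumeration", {
  coll <- toy_collection()
  # query of 4 universe genes overlapping T1 in 3
  query <- c("g01", "g02", "g03", "g06")
  res <- hypergeometric_enrich(query, coll, min_overlap = 2)
  p_t1 <- res$p_value[res$term_id == "T1"]
  expect_equal(p_t1, 155 / 4845, tolerance = 1e-12)
  expect_equal(p_t1, enumeration_hyper_p(N = 20, K_term = 5, n_query = 4, k = 3),
               tolerance = 1e-12)

  # term equal to the universe always overlaps: p = 1
  expect_equal(res$p_value[res$term_id == "T2"], 1)

  # overlap below min_overlap: absent from the output
  expect_false("T3" %in% res$term_id)
})

test_that("hypergeometric p agrees with enumeration across overlap sizes", {
  universe <- sprintf("u%02d", 1:12)
  coll <- annotation_collection(list(A = universe[1:6], PAD = universe))
  for (k in 2:5) {
    query <- c(universe[1:k], universe[seq.int(7, 7 + (5 - k))])  # 6 genes, k in A
    res <- hypergeometric_enrich(query, coll, min_overlap = 2)
    expect_equal(res$p_value[res$term_id == "A"],
                 enumeration_hyper_p(12, 6, 6, k), tolerance = 1e-12)
  }
})

test_that("p-values are monotone decreasing in the overlap", {
  ps <- vapply(2:6, function(k) {
    phyper(k - 1, 10, 90, 15, lower.tail = FALSE)
  }, 0)
  expect_true(all(diff(ps) < 0))
  # and BH q preserves p ordering
  coll <- toy_collection()
  res <- hypergeometric_enrich(c("g01", "g02", "g03", "g06"), coll)
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-15))
  expect_true(all(res$q_value <= 1))
})

test_that("kappa agreement scores match hand-worked values", {
  u6 <- paste0("g", 1:6)
  expect_equal(kappa_score(c("g1", "g2"), c("g1", "g2"), u6), 1)
  # disjoint halves of the universe: perfect disagreement
  u4 <- paste0("g", 1:4)
  expect_equal(kappa_score(c("g1", "g2"), c("g3", "g4"), u4), -1)
  # A = {g1,g2}, B = {g2,g3} in a 6-gene universe:
  # po = 4/6, pe = (2*2 + 4*4)/36 -> kappa = 0.25
  expect_equal(kappa_score(c("g1", "g2"), c("g2", "g3"), u6), 0.25)
  # degenerate: both terms cover the whole universe
  expect_warning(k0 <- kappa_score(u6, u6, u6), "degenerate")
  expect_equal(k0, 0)
})

test_that("kappa matrix is symmetric with unit diagonal", {
  coll <- annotation_collection(list(A = c("g1", "g2", "g3"),
                                     B = c("g2", "g3", "g4"),
                                     C = c("g5", "g6")))
  res <- data.frame(term_id = c("A", "B", "C"), p_value = c(0.01, 0.02, 0.03))
  km <- kappa_matrix(res, coll)
  expect_equal(km, t(km))
  expect_equal(unname(diag(km)), rep(1, 3))
  expect_equal(km["A", "B"], kappa_score(coll$terms$A, coll$terms$B,
                                         coll$universe))
})

test_that("term clustering follows the kappa threshold and is order-invariant", {
  # three near-identical terms plus one unrelated: 2 clusters at 0.4
  terms <- list(A1 = c("g1", "g2", "g3", "g4"),
                A2 = c("g1", "g2", "g3", "g5"),
                A3 = c("g1", "g2", "g4", "g5"),
                B1 = c("h1", "h2", "h3", "h4"))
  filler <- list(BG = sprintf("f%02d", 1:40))
  coll <- annotation_collection(c(terms, filler))
  query <- c("g1", "g2", "g3", "g4", "h1", "h2", "h3")
  res <- hypergeometric_enrich(query, coll, min_overlap = 2, p_cutoff = 0.05)
  expect_identical(sum(res$significant), 4L)
  out <- cluster_terms(res, coll, kappa_threshold = 0.4)
  expect_identical(attr(out, "n_clusters"), 2L)
  sig <- out[out$significant, ]
  expect_identical(length(unique(sig$cluster_id[startsWith(sig$term_id, "A")])), 1L)
  expect_false(any(sig$cluster_id[sig$term_id == "B1"] %in%
                     sig$cluster_id[startsWith(sig$term_id, "A")]))

  # shuffled input order gives the same clustering
  coll2 <- annotation_collection(c(filler, rev(terms)))
  res2 <- hypergeometric_enrich(query, coll2, min_overlap = 2, p_cutoff = 0.05)
  out2 <- cluster_terms(res2, coll2, kappa_threshold = 0.4)
  expect_identical(out2[order(out2$term_id), c("term_id", "cluster_id")],
                   out[order(out$term_id), c("term_id", "cluster_id")],
                   ignore_attr = TRUE)

  # all pairwise kappa above the threshold collapses to one cluster
  collA <- annotation_collection(c(terms[c("A1", "A2", "A3")], filler))
  resA <- hypergeometric_enrich(c("g1", "g2", "g3", "g4"), collA,
                                min_overlap = 2, p_cutoff = 0.05)
  oneA <- cluster_terms(resA, collA, kappa_threshold = 0.1)
  expect_identical(attr(oneA, "n_clusters"), 1L)

  # all pairwise kappa below the threshold: every term its own cluster
  km <- kappa_matrix(out[out$significant, ], coll)
  hi <- max(km[km < 1])
  apart <- cluster_terms(res, coll, kappa_threshold = min(hi + 0.01, 0.99))
  expect_identical(attr(apart, "n_clusters"), sum(res$significant))
})

test_that("GMT files round-trip through read and write", {
  coll <- annotation_collection(
    list(TERM1 = c("GATA3", "TXN"), TERM2 = c("CCR7", "CD28", "GATA3")),
    term_names = c(TERM1 = "response to nitric oxide",
                   TERM2 = "inflammatory response"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(back$terms, coll$terms)
  expect_identical(unname(back$term_names), unname(coll$term_names))
  expect_identical(back$universe, coll$universe)

  writeLines("ONLY_TWO\tfields", path)
  expect_error(read_gmt(path), "malformed GMT line 1")
})

test_that("empty or non-overlapping queries are rejected", {
  coll <- toy_collection()
  expect_error(hypergeometric_enrich(c("nope1", "nope2"), coll),
               "does not intersect")
})
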