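# Independent oracles and graph builders used across the suite.

# Brute-force betweenness: enumerate every shortest path between every
# unordered pair by backtracking over BFS distances, and for each pair add
# 1/(#shortest paths) to every interior node. Deliberately naive; only the
# BFS distance computation is shared with nothing in the package.
bruteforce_betweenness <- function(gr, normalized = TRUE) {
  n <- igraph::vcount(gr)
  nm <- igraph::V(gr)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  adj <- lapply(igraph::as_adj_list(gr, mode = "all"), as.integer)
  raw <- stats::setNames(numeric(n), nm)
  if (n < 3) return(raw)

  bfs_dist <- function(s) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    dist
  }

  enumerate_paths <- function(t, s, dist) {
    # all shortest s -> t paths, walking backwards from t
    if (t == s) return(list(s))
    preds <- adj[[t]][!is.na(dist[adj[[t]]]) & dist[adj[[t]]] == dist[t] - 1L]
    out <- list()
    for (p in preds) {
      for (sub in enumerate_paths(p, s, dist)) {
        out[[length(out) + 1]] <- c(sub, t)
      }
    }
    out
  }

  for (s in seq_len(n - 1)) {
    dist <- bfs_dist(s)
    for (t in seq.int(s + 1, n)) {
      if (is.na(dist[t])) next
      paths <- enumerate_paths(t, s, dist)
      npaths <- length(paths)
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        if (length(interior) > 0) {
          raw[interior] <- raw[interior] + 1 / npaths
        }
      }
    }
  }
  if (normalized) raw <- raw * 2 / ((n - 1) * (n - 2))
  raw
}

# Connected Erdos-Renyi graph (resample until connected), named vertices.
random_connected_gnp <- function(n, p) {
  repeat {
    gr <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(gr)) break
  }
  igraph::set_vertex_attr(gr, "name", value = sprintf("V%02d", seq_len(n)))
}

random_pa_graph <- function(n, m = 2) {
  gr <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  igraph::set_vertex_attr(gr, "name", value = sprintf("V%02d", seq_len(n)))
}

# small named graph from an edge list, as an InteractionNetwork-like igraph
graph_from_edges <- function(..., nodes = NULL) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  if (is.null(nodes)) nodes <- sort(unique(as.vector(e)))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = e[, 1], to = e[, 2]), directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::V(gr)$role <- "query"
  gr
}

as_network <- function(gr, provenance = list()) {
  structure(list(graph = gr, provenance = provenance),
            class = "InteractionNetwork")
}

# write a small TSV expression fixture and return its path
write_expression_fixture <- function(df, dir = tempdir()) {
  path <- tempfile("expr", tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# exhaustive hypergeometric upper tail: enumerate all n_query-subsets of the
# universe and count those overlapping the term in >= k genes
enumeration_hyper_p <- function(N, K_term, n_query, k) {
  universe <- seq_len(N)
  term <- seq_len(K_term)
  subsets <- utils::combn(universe, n_query)
  hits <- apply(subsets, 2, function(s) sum(s %in% term) >= k)
  mean(hits)
}
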