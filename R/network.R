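#' Load an interaction database from a STRING-dialect edge list
#'
#' Reads a three-column (node1, node2, combined_score) whitespace- or
#' tab-separated edge list, as in STRING `protein.links` exports; a single
#' header line is tolerated. Scores are integer confidence values in
#' \[0, 1000\]. Self-loops are dropped, duplicate unordered pairs are collapsed
#' keeping the maximum score, and edges below `score_threshold` are removed.
#'
#' @param path Path to the edge list.
#' @param score_threshold Minimum retained confidence score (default 400,
#'   STRING "medium confidence").
#' @return An `InteractionDatabase`: list with `edges` (data frame `node1`,
#'   `node2`, `score`), `nodes` (universe of node ids) and `score_threshold`.
#' @export
load_database <- function(path, score_threshold = 400) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty interaction database file: ", path, call. = FALSE)
    return(interaction_database(data.frame(node1 = character(),
                                           node2 = character(),
                                           score = integer()),
                                score_threshold))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(parts[[1]][3])))) start <- 2L  # header
  if (start > length(parts)) {
    warning("interaction database has a header but no rows: ", path, call. = FALSE)
    return(interaction_database(data.frame(node1 = character(),
                                           node2 = character(),
                                           score = integer()),
                                score_threshold))
  }
  rows <- parts[start:length(parts)]
  nfield <- lengths(rows)
  if (any(nfield != 3)) {
    bad <- which(nfield != 3)[1] + start - 1L
    stop(sprintf("malformed interaction row at line %d: expected 3 fields, got %d",
                 bad, nfield[which(nfield != 3)[1]]), call. = FALSE)
  }
  node1 <- vapply(rows, `[[`, "", 1L)
  node2 <- vapply(rows, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1] + start - 1L
    stop(sprintf("non-numeric score at line %d", bad), call. = FALSE)
  }
  if (any(score < 0 | score > 1000)) {
    bad <- which(score < 0 | score > 1000)[1] + start - 1L
    stop(sprintf("score outside [0, 1000] at line %d", bad), call. = FALSE)
  }
  interaction_database(data.frame(node1 = node1, node2 = node2,
                                  score = as.integer(round(score)),
                                  stringsAsFactors = FALSE),
                       score_threshold)
}

#' Construct an interaction database from an edge data frame
#'
#' Applies the same cleanup as [load_database()]: self-loop removal,
#' max-score deduplication of unordered pairs, score thresholding.
#'
#' @param edges Data frame with columns `node1`, `node2`, `score`.
#' @param score_threshold Minimum retained confidence score.
#' @export
interaction_database <- function(edges, score_threshold = 400) {
  edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
  if (nrow(edges) > 0) {
    a <- pmin(edges$node1, edges$node2)
    b <- pmax(edges$node1, edges$node2)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -edges$score)
    keep <- ord[!duplicated(key[ord])]
    edges <- data.frame(node1 = a[keep], node2 = b[keep],
                        score = edges$score[keep], stringsAsFactors = FALSE)
    edges <- edges[edges$score >= score_threshold, , drop = FALSE]
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$node1, edges$node2))),
                 score_threshold = score_threshold),
            class = "InteractionDatabase")
}

#' Write an interaction database as a 3-column TSV
#' @param db An `InteractionDatabase`.
#' @param path Output path.
#' @export
write_database <- function(db, path) {
  out <- db$edges
  colnames(out) <- c("node1", "node2", "combined_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_interaction_network <- function(graph, provenance) {
  structure(list(graph = graph, provenance = provenance),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  role <- igraph::V(x$graph)$role
  cat(sprintf("InteractionNetwork: %d nodes (%d query, %d neighbor), %d edges\n",
              igraph::vcount(x$graph), sum(role == "query"),
              sum(role == "neighbor"), igraph::ecount(x$graph)))
  for (nm in names(x$provenance)) {
    v <- x$provenance[[nm]]
    if (length(v) == 1 && is.numeric(v)) cat(sprintf("  %s: %d\n", nm, v))
  }
  invisible(x)
}

#' Induce the query-gene subgraph of an interaction database
#'
#' Maps a query gene set onto the database universe and returns the subgraph
#' on the mapped genes (database edges among them, confidence kept as edge
#' weight). Query genes absent from the database are reported as
#' unrecognized, mirroring the mapping-rate report of PPI tools.
#'
#' @param db An `InteractionDatabase`.
#' @param query Character vector of query gene ids (non-empty).
#' @return An `InteractionNetwork`: igraph graph whose nodes carry a `role`
#'   attribute (`"query"` here), plus a `provenance` list with
#'   `n_query_input`, `n_query_mapped`, `unrecognized`.
#' @export
induce_query_network <- function(db, query) {
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query gene set", call. = FALSE)
  mapped <- sort(intersect(query, db$nodes))
  unrecognized <- sort(setdiff(query, db$nodes))
  e <- db$edges[db$edges$node1 %in% mapped & db$edges$node2 %in% mapped, ,
                drop = FALSE]
  gr <- igraph::graph_from_data_frame(
    e[, c("node1", "node2")], directed = FALSE,
    vertices = data.frame(name = mapped, stringsAsFactors = FALSE))
  igraph::E(gr)$score <- e$score
  igraph::V(gr)$role <- "query"
  new_interaction_network(gr, list(
    n_query_input = length(query),
    n_query_mapped = length(mapped),
    unrecognized = unrecognized))
}

#' Rank and add first neighbors to a query network
#'
#' Candidate neighbors are database nodes adjacent to at least one query node
#' (and not query themselves), ranked by (number of distinct query-node
#' connections desc, summed confidence of query-incident edges desc, node id
#' asc). The top `m` are added with role `"neighbor"`, and all database edges
#' among the enlarged node set are materialized. This deterministic rule
#' stands in for the "add first neighbors" step of interactive PPI tools; it
#' never removes nodes or edges.
#'
#' @param db The `InteractionDatabase` the network was induced from.
#' @param net An `InteractionNetwork` of query nodes.
#' @param m Number of neighbors to add (default 20). If fewer candidates
#'   exist, all are added and the shortfall logged as a warning.
#' @export
add_first_neighbors <- function(db, net, m = 20) {
  stopifnot(m >= 0)
  query <- igraph::V(net$graph)$name[igraph::V(net$graph)$role == "query"]
  prov <- net$provenance
  if (m == 0) {
    prov$n_neighbors_added <- 0L
    return(new_interaction_network(net$graph, prov))
  }
  e <- db$edges
  inc1 <- e$node1 %in% query
  inc2 <- e$node2 %in% query
  cand_edges <- e[xor(inc1, inc2) | (inc1 & inc2), , drop = FALSE]
  # per-candidate stats over query-incident edges
  cand <- character(0); nconn <- integer(0); sconf <- numeric(0)
  touch1 <- cand_edges[cand_edges$node2 %in% query &
                         !(cand_edges$node1 %in% query), , drop = FALSE]
  touch2 <- cand_edges[cand_edges$node1 %in% query &
                         !(cand_edges$node2 %in% query), , drop = FALSE]
  inc <- rbind(data.frame(cand = touch1$node1, q = touch1$node2, s = touch1$score),
               data.frame(cand = touch2$node2, q = touch2$node1, s = touch2$score))
  if (nrow(inc) > 0) {
    agg_n <- tapply(inc$q, inc$cand, function(q) length(unique(q)))
    agg_s <- tapply(inc$s, inc$cand, sum)
    cand <- names(agg_n)
    nconn <- as.integer(agg_n)
    sconf <- as.numeric(agg_s[cand])
  }
  ord <- order(-nconn, -sconf, cand)
  picked <- cand[utils::head(ord, m)]
  if (length(cand) < m) {
    warning(sprintf("only %d neighbor candidate(s) available (requested %d)",
                    length(cand), m), call. = FALSE)
  }
  nodes <- data.frame(name = c(sort(query), sort(picked)),
                      role = c(rep("query", length(query)),
                               rep("neighbor", length(picked))),
                      stringsAsFactors = FALSE)
  sub <- e[e$node1 %in% nodes$name & e$node2 %in% nodes$name, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(sub[, c("node1", "node2")],
                                      directed = FALSE, vertices = nodes)
  igraph::E(gr)$score <- sub$score
  prov$n_neighbors_added <- length(picked)
  new_interaction_network(gr, prov)
}

#' Extract the main connected component
#'
#' Keeps the largest connected component by node count (ties broken by the
#' component containing the lexicographically smallest node id) and reports
#' every excluded node — typically the isolated query genes that motivated
#' neighbor augmentation in the first place.
#'
#' @param net An `InteractionNetwork`.
#' @return The connected `InteractionNetwork`, with `provenance` extended by
#'   `n_main_component`, `n_query_isolated_removed`, and an `excluded` data
#'   frame (`node_id`, `role`).
#' @export
main_component <- function(net) {
  gr <- net$graph
  if (igraph::vcount(gr) == 0) stop("empty network", call. = FALSE)
  comp <- igraph::components(gr)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    smallest <- vapply(best, function(ci) {
      min(igraph::V(gr)$name[comp$membership == ci])
    }, "")
    best <- best[order(smallest)][1]
  }
  keep <- comp$membership == best
  excluded <- data.frame(node_id = igraph::V(gr)$name[!keep],
                         role = igraph::V(gr)$role[!keep],
                         stringsAsFactors = FALSE)
  excluded <- excluded[order(excluded$node_id), , drop = FALSE]
  rownames(excluded) <- NULL
  sub <- igraph::induced_subgraph(gr, which(keep))
  prov <- net$provenance
  prov$n_main_component <- as.integer(igraph::vcount(sub))
  prov$n_query_isolated_removed <- as.integer(sum(excluded$role == "query"))
  prov$excluded <- excluded
  new_interaction_network(sub, prov)
}

#' Scale-free diagnostic for a network
#'
#' Fits `log10 P(k) ~ log10 k` by least squares over observed degrees k >= 1
#' (degree histogram normalized to a probability over the non-isolated
#' nodes). The verdict is `"scale-free-like"` iff the slope lies in
#' `slope_range`, the fit r-squared reaches `min_r_squared`, and at most
#' `max_isolated` of the nodes are isolated; otherwise `"not scale-free"`.
#' An isolated fraction above 0.3 is additionally annotated as
#' `"weak interactions"`, the situation in which sparse seed networks are
#' usually augmented with first neighbors.
#'
#' @param net An `InteractionNetwork` or an igraph graph.
#' @param slope_range Acceptable power-law slope interval (default c(-3, -1)).
#' @param min_r_squared Minimum fit quality (default 0.7).
#' @param max_isolated Maximum isolated-node fraction (default 0.1).
#' @return List with `slope`, `r_squared`, `isolated_fraction`, `verdict`,
#'   `note`.
#' @export
scale_free_check <- function(net, slope_range = c(-3, -1),
                             min_r_squared = 0.7, max_isolated = 0.1) {
  gr <- if (inherits(net, "InteractionNetwork")) net$graph else net
  deg <- igraph::degree(gr)
  iso <- mean(deg == 0)
  note <- if (iso > 0.3) "weak interactions" else ""
  pos <- deg[deg >= 1]
  if (length(pos) == 0) {
    return(list(slope = NA_real_, r_squared = NA_real_, isolated_fraction = iso,
                verdict = "not scale-free", note = note))
  }
  tab <- table(pos)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(pos)
  if (length(k) < 2) {
    return(list(slope = NA_real_, r_squared = NA_real_, isolated_fraction = iso,
                verdict = "not scale-free", note = note))
  }
  fit <- stats::lm(log10(pk) ~ log10(k))
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (length(k) == 2) 1 else summary(fit)$r.squared
  ok <- slope >= slope_range[1] && slope <= slope_range[2] &&
    r2 >= min_r_squared && iso <= max_isolated
  list(slope = slope, r_squared = r2, isolated_fraction = iso,
       verdict = if (ok) "scale-free-like" else "not scale-free", note = note)
}

#' Write a network in SIF format (`nodeA<TAB>pp<TAB>nodeB`)
#' @param net An `InteractionNetwork`.
#' @param path Output path.
#' @export
write_sif <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  lines <- if (nrow(el) > 0) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b)
    sprintf("%s\tpp\t%s", a[ord], b[ord])
  } else character(0)
  # isolated nodes appear as bare node lines so the node set round-trips
  iso <- igraph::V(net$graph)$name[igraph::degree(net$graph) == 0]
  writeLines(c(lines, sort(iso)), path)
  invisible(path)
}

#' Write a network as GraphML with role, degree and betweenness attributes
#' @param net An `InteractionNetwork`.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  gr <- net$graph
  igraph::V(gr)$degree <- as.numeric(igraph::degree(gr))
  bc <- rep(NA_real_, igraph::vcount(gr))
  comp <- igraph::components(gr)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(gr, idx)
    bc[idx] <- betweenness_brandes(sub)[igraph::V(sub)$name]
  }
  igraph::V(gr)$betweenness <- bc
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
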