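#' Select hub genes (top decile by degree)
#'
#' Restricts the centrality table to the query genes, takes
#' `k_top = ceiling(fraction * n_query)` and returns the first `k_top` genes
#' sorted by (K desc, BC desc, node_id asc). With the default fraction 0.10 a
#' 39-gene query component yields exactly 4 hubs. Only query genes are
#' eligible: added neighbors connect the component but are not candidate
#' disease genes.
#'
#' @param table A `CentralityTable`.
#' @param query_ids Query gene ids (must appear in `table`).
#' @param fraction Top fraction to keep, in (0, 1\] (default 0.10).
#' @return Data frame of the selected rows in rank order.
#' @export
select_hubs <- function(table, query_ids, fraction = 0.10) {
  select_top_decile(table, query_ids, fraction, key = "K")
}

#' Select bottleneck genes (top decile by betweenness)
#'
#' As [select_hubs()] with sort key (BC desc, K desc, node_id asc).
#'
#' @inheritParams select_hubs
#' @export
select_bottlenecks <- function(table, query_ids, fraction = 0.10) {
  select_top_decile(table, query_ids, fraction, key = "BC")
}

select_top_decile <- function(table, query_ids, fraction, key) {
  stopifnot(fraction > 0, fraction <= 1)
  query_ids <- unique(as.character(query_ids))
  if (length(query_ids) == 0) stop("empty query gene set", call. = FALSE)
  missing <- setdiff(query_ids, table$node_id)
  if (length(missing) > 0) {
    stop("query ids absent from centrality table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- table[table$node_id %in% query_ids, , drop = FALSE]
  k_top <- ceiling(fraction * nrow(sub))
  ord <- if (key == "K") order(-sub$K, -sub$BC, sub$node_id)
         else order(-sub$BC, -sub$K, sub$node_id)
  out <- utils::head(sub[ord, , drop = FALSE], k_top)
  rownames(out) <- NULL
  out
}

#' Classify query genes as hubs, bottlenecks and hub-bottlenecks
#'
#' Crucial genes are the union of the hub and bottleneck lists;
#' hub-bottlenecks their intersection. Each crucial gene gets a
#' classification row with its ranks under both orderings.
#'
#' @param hubs,bottlenecks Outputs of [select_hubs()] /
#'   [select_bottlenecks()] drawn from the same query set.
#' @param table The `CentralityTable` both were selected from (used for
#'   ranks; defaults to the union of the two lists).
#' @param query_ids Query gene set used for ranking (defaults to the union).
#' @return A list of class `NodeClassification` with `classification` (data
#'   frame: `node_id`, `K`, `BC`, `is_hub`, `is_bottleneck`,
#'   `is_hub_bottleneck`, `rank_by_K`, `rank_by_BC`), `crucial` (union, in
#'   (K desc, BC desc, id) order), `hub_bottlenecks` (intersection), and the
#'   input lists.
#' @export
classify_nodes <- function(hubs, bottlenecks, table = NULL, query_ids = NULL) {
  crucial_ids <- union(hubs$node_id, bottlenecks$node_id)
  if (is.null(table)) {
    table <- unique(rbind(as.data.frame(hubs), as.data.frame(bottlenecks)))
  }
  if (is.null(query_ids)) query_ids <- intersect(table$node_id, crucial_ids)
  sub <- table[table$node_id %in% query_ids, , drop = FALSE]
  rk_K <- sub$node_id[order(-sub$K, -sub$BC, sub$node_id)]
  rk_BC <- sub$node_id[order(-sub$BC, -sub$K, sub$node_id)]
  rows <- table[match(crucial_ids, table$node_id), , drop = FALSE]
  cls <- data.frame(node_id = rows$node_id,
                    K = rows$K, BC = rows$BC,
                    is_hub = rows$node_id %in% hubs$node_id,
                    is_bottleneck = rows$node_id %in% bottlenecks$node_id,
                    stringsAsFactors = FALSE)
  cls$is_hub_bottleneck <- cls$is_hub & cls$is_bottleneck
  cls$rank_by_K <- match(cls$node_id, rk_K)
  cls$rank_by_BC <- match(cls$node_id, rk_BC)
  cls <- cls[order(-cls$K, -cls$BC, cls$node_id), , drop = FALSE]
  rownames(cls) <- NULL
  structure(list(classification = cls,
                 crucial = cls$node_id,
                 hub_bottlenecks = sort(intersect(hubs$node_id,
                                                  bottlenecks$node_id)),
                 hubs = hubs$node_id,
                 bottlenecks = bottlenecks$node_id),
            class = "NodeClassification")
}

#' @export
print.NodeClassification <- function(x, ...) {
  cat(sprintf("Crucial genes: %d (hubs %d, bottlenecks %d, hub-bottlenecks %d)\n",
              length(x$crucial), length(x$hubs), length(x$bottlenecks),
              length(x$hub_bottlenecks)))
  if (length(x$hub_bottlenecks) > 0) {
    cat("  hub-bottleneck:", paste(x$hub_bottlenecks, collapse = ", "), "\n")
  }
  print(x$classification)
  invisible(x)
}

#' Write a classification table
#' @param cls A `NodeClassification`.
#' @param path Output path.
#' @export
write_classification <- function(cls, path) {
  utils::write.table(cls$classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
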