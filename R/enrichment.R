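#' Construct an annotation collection
#'
#' @param terms Named list of character vectors: `term_id -> gene set`. Every
#'   set must be non-empty; ids unique.
#' @param term_names Optional named character vector of human-readable term
#'   names (defaults to the ids).
#' @param background Optional gene universe to intersect with; by default the
#'   universe is the union of all term genes.
#' @return An `AnnotationCollection`: list with `terms`, `term_names`,
#'   `universe`.
#' @export
annotation_collection <- function(terms, term_names = NULL, background = NULL) {
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    stop("`terms` must be a uniquely named list", call. = FALSE)
  }
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  universe <- sort(unique(unlist(terms, use.names = FALSE)))
  if (!is.null(background)) {
    universe <- intersect(universe, as.character(background))
    terms <- lapply(terms, intersect, universe)
  }
  if (any(lengths(terms) == 0)) {
    stop("empty term gene set(s): ",
         paste(names(terms)[lengths(terms) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms,
                 term_names = term_names[names(terms)],
                 universe = universe),
            class = "AnnotationCollection")
}

#' Read annotation term sets from a GMT file
#'
#' GMT: one term per line, `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @param background Optional background gene universe.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    stop(sprintf("malformed GMT line %d: need term, description, >= 1 gene",
                 short[1]), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  descr <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  annotation_collection(stats::setNames(genes, ids),
                        term_names = stats::setNames(descr, ids),
                        background = background)
}

#' Write an annotation collection as GMT
#' @param coll An `AnnotationCollection`.
#' @param path Output path.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$terms), function(id) {
    paste(c(id, coll$term_names[[id]], coll$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test of a gene list
#'
#' For each term with overlap `k >= min_overlap`, tests whether the query
#' list overlaps the term's gene set more than expected by chance:
#' `p = P[X >= k]`, `X ~ Hypergeometric(N, K_term, n_query)`, with `N` the
#' universe size and the query restricted to the universe. p-values are BH
#' adjusted across all tested terms; `significant` flags raw
#' `p <= p_cutoff`.
#'
#' @param query Character vector of query genes (the crucial genes).
#' @param coll An [annotation_collection()].
#' @param min_overlap Minimum overlap for a term to be tested (default 2).
#' @param p_cutoff Significance threshold on the raw p-value (default 0.05).
#' @return An `EnrichmentResult` data frame sorted by `(p_value, term_id)`:
#'   `term_id`, `term_name`, `k`, `K_term`, `n_query`, `N`, `overlap_genes`
#'   (comma-separated), `p_value`, `q_value`, `significant`, `cluster_id`
#'   (NA until [cluster_terms()]).
#' @export
hypergeometric_enrich <- function(query, coll, min_overlap = 2,
                                  p_cutoff = 0.05) {
  if (length(coll$universe) == 0) stop("empty annotation universe", call. = FALSE)
  query <- intersect(unique(as.character(query)), coll$universe)
  if (length(query) == 0) {
    stop("query does not intersect the annotation universe", call. = FALSE)
  }
  N <- length(coll$universe)
  nq <- length(query)
  rows <- lapply(names(coll$terms), function(id) {
    genes <- coll$terms[[id]]
    ov <- intersect(query, genes)
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    Kt <- length(genes)
    p <- stats::phyper(k - 1, Kt, N - Kt, nq, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(coll$term_names[[id]]),
               k = k, K_term = Kt, n_query = nq, N = N,
               overlap_genes = paste(sort(ov), collapse = ","),
               p_value = min(max(p, .Machine$double.xmin), 1),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(term_id = character(), term_name = character(),
                       k = integer(), K_term = integer(), n_query = integer(),
                       N = integer(), overlap_genes = character(),
                       p_value = numeric(), stringsAsFactors = FALSE)
  }
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$p_value <= p_cutoff
  rows$cluster_id <- rep(NA_integer_, nrow(rows))
  rows <- rows[order(rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("EnrichmentResult", "data.frame")
  rows
}

#' Cohen's kappa between two gene memberships over a universe
#'
#' Chance-corrected agreement of the 2x2 membership table of universe genes.
#' A degenerate table (expected agreement 1, e.g. a term covering the whole
#' universe compared with itself-complementary sets) yields kappa 0 with a
#' warning.
#'
#' @param set1,set2 Character vectors (subsets of `universe`).
#' @param universe Gene universe.
#' @export
kappa_score <- function(set1, set2, universe) {
  n <- length(universe)
  in1 <- universe %in% set1
  in2 <- universe %in% set2
  a <- sum(in1 & in2); b <- sum(in1 & !in2)
  c_ <- sum(!in1 & in2); d <- sum(!in1 & !in2)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (pe == 1) {
    warning("degenerate membership table; kappa set to 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Pairwise kappa matrix of enrichment terms
#'
#' Symmetric matrix of [kappa_score()] between the gene memberships of the
#' supplied terms over the collection's universe; unit diagonal.
#'
#' @param results An `EnrichmentResult` (typically its significant rows).
#' @param coll The [annotation_collection()] the results came from.
#' @export
kappa_matrix <- function(results, coll) {
  ids <- results$term_id
  if (length(ids) == 0) stop("no terms to compare", call. = FALSE)
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        kap <- kappa_score(coll$terms[[ids[i]]], coll$terms[[ids[j]]],
                           coll$universe)
        m[i, j] <- kap
        m[j, i] <- kap
      }
    }
  }
  m
}

#' Group significant terms into kappa clusters
#'
#' Builds a graph on the significant terms with edges where pairwise kappa
#' >= `kappa_threshold`; connected components are the clusters (so a cluster
#' is a chain of mutually overlapping terms, the grouping mechanism of
#' functional-enrichment tools). Clusters are numbered by their best (lowest)
#' p-value and each is labeled by its best term. Singleton terms form their
#' own clusters. Non-significant terms keep `cluster_id = NA`.
#'
#' @param results An `EnrichmentResult`.
#' @param coll The [annotation_collection()] the results came from.
#' @param kappa_threshold Edge threshold in (0, 1) (default 0.4).
#' @return `results` with `cluster_id` filled in, plus attributes `n_clusters`
#'   and `cluster_labels` (named by cluster id).
#' @export
cluster_terms <- function(results, coll, kappa_threshold = 0.4) {
  stopifnot(kappa_threshold > 0, kappa_threshold < 1)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    attr(results, "n_clusters") <- 0L
    attr(results, "cluster_labels") <- character(0)
    return(results)
  }
  km <- kappa_matrix(sig, coll)
  adj <- km >= kappa_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  membership <- comp$membership[sig$term_id]
  # renumber clusters by best p, then term id, for order-invariance
  best_p <- tapply(sig$p_value, membership, min)
  best_id <- tapply(sig$term_id, membership, min)
  ord <- order(best_p, best_id)
  renum <- stats::setNames(seq_along(ord), names(best_p)[ord])
  cluster_id <- as.integer(renum[as.character(membership)])
  results$cluster_id[match(sig$term_id, results$term_id)] <- cluster_id
  labels <- vapply(seq_along(ord), function(ci) {
    members <- sig[cluster_id == ci, , drop = FALSE]
    members$term_name[order(members$p_value, members$term_id)][1]
  }, "")
  attr(results, "n_clusters") <- length(ord)
  attr(results, "cluster_labels") <- stats::setNames(labels, seq_along(ord))
  results
}

#' Write an enrichment result table
#' @param results An `EnrichmentResult`.
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
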