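#' Pipeline configuration
#'
#' Collects the file paths and thresholds of a full prioritization run.
#' Defaults are the workflow's canonical settings: top 250 genes by p-value,
#' significance at fold change > 2 and p <= 0.05, interaction confidence
#' >= 400, 20 added first neighbors, top decile for hub/bottleneck calls,
#' kappa threshold 0.4 and minimum term overlap 2.
#'
#' @param expression,sample_map,database,gmt Input file paths (`gmt` may be
#'   `NULL` to skip enrichment).
#' @param outdir Output directory.
#' @param top_n,fc_cutoff,p_cutoff,score_threshold,n_neighbors,top_fraction,kappa_threshold,min_overlap,comparability_tol
#'   Stage thresholds (see the stage functions).
#' @param case,control Group labels in the sample map.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(expression, sample_map, database, gmt = NULL,
                            outdir = ".",
                            top_n = 250, fc_cutoff = 2, p_cutoff = 0.05,
                            score_threshold = 400, n_neighbors = 20,
                            top_fraction = 0.10, kappa_threshold = 0.4,
                            min_overlap = 2, comparability_tol = 0.5,
                            case = "case", control = "control") {
  stopifnot(top_n >= 1, fc_cutoff > 0, p_cutoff > 0, p_cutoff <= 1,
            score_threshold >= 0, score_threshold <= 1000, n_neighbors >= 0,
            top_fraction > 0, top_fraction <= 1,
            kappa_threshold > 0, kappa_threshold < 1, min_overlap >= 1,
            comparability_tol > 0)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full prioritization pipeline
#'
#' Executes differential expression -> network construction and neighbor
#' augmentation -> main-component centrality -> hub/bottleneck
#' classification -> (optionally) term enrichment with kappa clustering,
#' writing every stage table under `cfg$outdir` and returning a run report
#' with the stage counts. The pipeline is deterministic: identical config and
#' inputs give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `PipelineReport`: per-stage counts
#'   (`n_genes`, `n_top`, `n_significant`, `n_query_mapped`,
#'   `n_neighbors_added`, `n_query_isolated_removed`, `n_main_component`,
#'   `k_top`, `hubs`, `bottlenecks`, `hub_bottlenecks`, `crucial`,
#'   `n_terms_significant`, `n_term_clusters`), QC report, and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)

  m <- read_expression(cfg$expression)
  g <- read_sample_groups(cfg$sample_map, case = cfg$case, control = cfg$control)
  qc <- check_comparability(m, tol = cfg$comparability_tol)

  deg <- differential_expression(m, g, fc_cutoff = cfg$fc_cutoff,
                                 p_cutoff = cfg$p_cutoff)
  top <- select_top(deg, n = cfg$top_n)
  write_deg_table(top, out("deg_top.tsv"))
  sig_genes <- top$gene_id[top$significant]

  db <- load_database(cfg$database, score_threshold = cfg$score_threshold)
  net <- induce_query_network(db, sig_genes)
  net <- add_first_neighbors(db, net, m = cfg$n_neighbors)
  main <- main_component(net)
  sf <- scale_free_check(main)
  write_sif(main, out("network.sif"))
  write_graphml(main, out("network.graphml"))

  ctab <- centrality_table(main)
  write_centrality_table(ctab, out("centrality.tsv"))
  query_in_comp <- ctab$node_id[ctab$role == "query"]
  hubs <- select_hubs(ctab, query_in_comp, fraction = cfg$top_fraction)
  bottlenecks <- select_bottlenecks(ctab, query_in_comp,
                                    fraction = cfg$top_fraction)
  cls <- classify_nodes(hubs, bottlenecks, table = ctab,
                        query_ids = query_in_comp)
  write_classification(cls, out("classification.tsv"))

  enr <- NULL
  n_sig_terms <- NA_integer_
  n_clusters <- NA_integer_
  if (!is.null(cfg$gmt)) {
    coll <- read_gmt(cfg$gmt)
    if (length(intersect(cls$crucial, coll$universe)) > 0) {
      enr <- hypergeometric_enrich(cls$crucial, coll,
                                   min_overlap = cfg$min_overlap,
                                   p_cutoff = cfg$p_cutoff)
      enr <- cluster_terms(enr, coll, kappa_threshold = cfg$kappa_threshold)
      write_enrichment(enr, out("enrichment.tsv"))
      n_sig_terms <- sum(enr$significant)
      n_clusters <- attr(enr, "n_clusters")
    } else {
      warning("no crucial gene occurs in the annotation universe; ",
              "enrichment skipped", call. = FALSE)
    }
  }

  prov <- main$provenance
  report <- structure(list(
    comparability_pass = qc$pass,
    n_genes = nrow(deg),
    n_top = nrow(top),
    n_significant = attr(top, "n_significant"),
    n_query_input = prov$n_query_input,
    n_query_mapped = prov$n_query_mapped,
    n_neighbors_added = prov$n_neighbors_added,
    n_query_isolated_removed = prov$n_query_isolated_removed,
    n_main_component = prov$n_main_component,
    scale_free_verdict = sf$verdict,
    k_top = nrow(hubs),
    hubs = hubs$node_id,
    bottlenecks = bottlenecks$node_id,
    hub_bottlenecks = cls$hub_bottlenecks,
    crucial = cls$crucial,
    n_terms_significant = n_sig_terms,
    n_term_clusters = n_clusters,
    outdir = cfg$outdir), class = "PipelineReport")
  jsonlite::write_json(report[setdiff(names(report), "outdir")],
                       out("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Prioritization pipeline report\n")
  cat(sprintf("  comparability: %s\n",
              if (x$comparability_pass) "pass" else "FAIL"))
  cat(sprintf("  genes tested: %d; top selected: %d; significant DEGs: %d\n",
              x$n_genes, x$n_top, x$n_significant))
  cat(sprintf("  query mapped: %d/%d; neighbors added: %d\n",
              x$n_query_mapped, x$n_query_input, x$n_neighbors_added))
  cat(sprintf("  isolated query genes removed: %d; main component: %d nodes (%s)\n",
              x$n_query_isolated_removed, x$n_main_component,
              x$scale_free_verdict))
  cat(sprintf("  top decile k = %d\n", x$k_top))
  cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  cat("  bottlenecks:", paste(x$bottlenecks, collapse = ", "), "\n")
  cat("  hub-bottlenecks:", paste(x$hub_bottlenecks, collapse = ", "), "\n")
  cat(sprintf("  crucial genes: %d\n", length(x$crucial)))
  if (!is.na(x$n_terms_significant)) {
    cat(sprintf("  significant terms: %d in %d cluster(s)\n",
                x$n_terms_significant, x$n_term_clusters))
  }
  invisible(x)
}
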