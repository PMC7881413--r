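#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' design of a two-group pediatric Crohn's disease transcriptomic study:
#' 20 cases vs 20 controls, 81 planted differentially expressed genes with
#' |log2 fold change| above 1 (so fold change above 2), of which 69 are
#' recognized by the interaction database and 39 end up in the main connected
#' component together with 20 added first neighbors.
#'
#' @param seed Integer seed; every generator is a pure function of its config.
#' @param n_genes Total genes in the expression matrix.
#' @param n_case,n_control Samples per group.
#' @param n_de Number of planted DE genes.
#' @param log2fc_range Interval the planted |log2fc| is drawn from; the lower
#'   bound must exceed 1 so every planted gene has fold change > 2.
#' @param noise_sd I.i.d. Gaussian noise SD on the log2 scale.
#' @param db_nodes Background nodes of the preferential-attachment backbone
#'   of the interaction database.
#' @param attachment Preferential-attachment parameter (edges per new node).
#' @param n_query_mapped Planted DE genes present in the database universe.
#' @param n_connectable Mapped genes wired to the neighbor anchors (the rest
#'   of the mapped genes are left isolated, mimicking sparse seed networks).
#' @param n_anchors Designated first-neighbor nodes connecting the query
#'   genes (the nodes the augmentation step should pick).
#' @param n_term_blocks,terms_per_block,core_size,periphery_per_term Structure
#'   of the planted annotation collection: blocks of terms sharing a gene
#'   core (high within-block kappa) and disjoint across blocks.
#' @param n_filler_terms,filler_term_size Background terms of filler genes
#'   that enlarge the annotation universe without overlapping the blocks,
#'   emulating the rest of an annotation catalogue.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000, n_case = 20, n_control = 20,
                       n_de = 81, log2fc_range = c(1.2, 3), noise_sd = 0.25,
                       db_nodes = 400, attachment = 2,
                       n_query_mapped = 69, n_connectable = 39, n_anchors = 20,
                       n_term_blocks = 3, terms_per_block = 6, core_size = 6,
                       periphery_per_term = 2, n_filler_terms = 3,
                       filler_term_size = 60) {
  stopifnot(n_genes >= 1, n_case >= 2, n_control >= 2,
            n_de >= 1, n_de <= n_genes,
            length(log2fc_range) == 2, log2fc_range[1] > 1,
            log2fc_range[1] <= log2fc_range[2],
            noise_sd >= 0, db_nodes >= 1, attachment >= 1,
            n_query_mapped <= n_de, n_connectable <= n_query_mapped,
            n_anchors >= 1, n_term_blocks >= 1, terms_per_block >= 2,
            core_size >= 2)
  structure(as.list(environment()), class = "SimulationConfig")
}

# evaluate expr with a locally seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a case/control expression matrix with planted DE genes
#'
#' Per-gene baselines are drawn from Normal(8, 1) (log2 intensity scale);
#' planted genes get a case-group shift of magnitude drawn uniformly from
#' `log2fc_range` with random sign; i.i.d. Normal(0, `noise_sd`) noise is
#' added everywhere. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `matrix` ([expression_matrix()]), `groups`
#'   ([sample_groups()]), `planted` (data frame `gene_id`, `log2fc` of the
#'   planted truth).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed, {
    gid <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    sid <- c(sprintf("CASE%02d", seq_len(cfg$n_case)),
             sprintf("CTRL%02d", seq_len(cfg$n_control)))
    grp <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
    vals <- matrix(baseline, nrow = cfg$n_genes, ncol = length(sid),
                   dimnames = list(gid, sid))
    de_idx <- sort(sample.int(cfg$n_genes, cfg$n_de))
    delta <- stats::runif(cfg$n_de, cfg$log2fc_range[1], cfg$log2fc_range[2]) *
      sample(c(-1, 1), cfg$n_de, replace = TRUE)
    vals[de_idx, grp == "case"] <- vals[de_idx, grp == "case"] + delta
    vals <- vals + matrix(stats::rnorm(length(vals), sd = cfg$noise_sd),
                          nrow = nrow(vals))
    list(matrix = expression_matrix(vals, log2_transformed = TRUE),
         groups = sample_groups(sid, grp),
         planted = data.frame(gene_id = gid[de_idx], log2fc = delta,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate an interaction database with planted topology
#'
#' Generates a STRING-dialect confidence-weighted edge set consisting of a
#' preferential-attachment backbone of background nodes, a ring of
#' `n_anchors` designated neighbor nodes, and wiring of the planted query
#' genes: `n_query_mapped` of them appear in the database universe,
#' `n_connectable` of those attach to anchors (a designated target gene to
#' every anchor, giving it maximal degree and betweenness among query genes;
#' the others to one or two anchors each), and the remaining mapped genes get
#' a single edge to a private low-confidence partner, leaving them isolated
#' once neighbors are ranked — the situation where sparse seed networks shed
#' isolated queries. All planted roles are returned as labeled truth.
#'
#' @param cfg A [sim_config()].
#' @param planted_query Character vector of query gene ids (e.g. the planted
#'   DE genes of [simulate_expression()]).
#' @return List: `db` (`InteractionDatabase`), `target` (the designated
#'   maximal-centrality query gene), `mapped`, `connectable`, `isolated`,
#'   `anchors`.
#' @export
simulate_database <- function(cfg, planted_query) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  planted_query <- unique(as.character(planted_query))
  stopifnot(length(planted_query) >= cfg$n_query_mapped)
  with_seed(cfg$seed + 1L, {
    mapped <- sort(sample(planted_query, cfg$n_query_mapped))
    connectable <- sort(sample(mapped, cfg$n_connectable))
    isolated <- setdiff(mapped, connectable)
    target <- sample(connectable, 1)
    others <- setdiff(connectable, target)
    anchors <- sprintf("NBR%02d", seq_len(cfg$n_anchors))
    bg <- sprintf("BG%04d", seq_len(cfg$db_nodes))

    backbone <- igraph::sample_pa(cfg$db_nodes, power = 1, m = cfg$attachment,
                                  directed = FALSE)
    el <- igraph::as_edgelist(backbone)
    edges <- data.frame(node1 = bg[as.integer(el[, 1])],
                        node2 = bg[as.integer(el[, 2])],
                        score = sample(400:999, nrow(el), replace = TRUE),
                        stringsAsFactors = FALSE)
    # anchor ring, mutually high confidence
    ring <- data.frame(node1 = anchors,
                       node2 = anchors[c(seq_len(cfg$n_anchors)[-1], 1L)],
                       score = 900L, stringsAsFactors = FALSE)
    # anchors touch the backbone so the database is one fabric
    anchor_bg <- data.frame(node1 = anchors,
                            node2 = sample(bg, cfg$n_anchors, replace = TRUE),
                            score = 700L, stringsAsFactors = FALSE)
    # the target attaches to every anchor: maximal degree, and the shortcut
    # between distant anchors gives it maximal betweenness among queries
    tgt <- data.frame(node1 = target, node2 = anchors, score = 950L,
                      stringsAsFactors = FALSE)
    # other connectable queries: one anchor round-robin, sometimes a second
    first <- anchors[(seq_along(others) - 1L) %% cfg$n_anchors + 1L]
    qe <- data.frame(node1 = others, node2 = first, score = 800L,
                     stringsAsFactors = FALSE)
    second_pick <- stats::runif(length(others)) < 0.5
    if (any(second_pick)) {
      qe2 <- data.frame(node1 = others[second_pick],
                        node2 = sample(anchors, sum(second_pick), replace = TRUE),
                        score = 800L, stringsAsFactors = FALSE)
      qe <- rbind(qe, qe2)
    }
    # isolated queries: a single private partner each, low confidence
    partners <- sprintf("PT%03d", seq_along(isolated))
    iso <- data.frame(node1 = isolated, node2 = partners, score = 500L,
                      stringsAsFactors = FALSE)
    db <- interaction_database(rbind(edges, ring, anchor_bg, tgt, qe, iso),
                               score_threshold = 400)
    # planted contract: the target out-degrees every other query gene
    dq <- table(factor(c(db$edges$node1[db$edges$node1 %in% mapped],
                         db$edges$node2[db$edges$node2 %in% mapped]),
                       levels = mapped))
    stopifnot(dq[target] > max(dq[names(dq) != target]))
    list(db = db, target = target, mapped = mapped,
         connectable = connectable, isolated = isolated, anchors = anchors)
  })
}

#' Simulate an annotation collection with planted term blocks
#'
#' Builds `n_term_blocks` blocks of `terms_per_block` terms each. Terms
#' within a block share a `core_size`-gene core (so pairwise kappa within a
#' block is high) plus a few private periphery genes; blocks are disjoint
#' (kappa across blocks near zero). The supplied `genes` (e.g. crucial genes
#' whose enrichment is of interest) are distributed round-robin into the
#' block cores so every block's terms overlap them. A handful of filler-only
#' background terms enlarge the universe, emulating the remainder of an
#' annotation catalogue.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of genes to seed into the block cores.
#' @return List: `collection` ([annotation_collection()]), `blocks` (named
#'   integer vector term_id -> planted block).
#' @export
simulate_annotations <- function(cfg, genes) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- unique(as.character(genes))
  nb <- cfg$n_term_blocks
  with_seed(cfg$seed + 2L, {
    block_of_gene <- rep(seq_len(nb), length.out = length(genes))
    terms <- list()
    descr <- character(0)
    blocks <- integer(0)
    peri_counter <- 0L
    for (b in seq_len(nb)) {
      seeded <- genes[block_of_gene == b]
      n_fill <- max(0L, cfg$core_size - length(seeded))
      core <- c(seeded, sprintf("CORE_B%d_G%02d", b, seq_len(n_fill)))
      for (t in seq_len(cfg$terms_per_block)) {
        peri <- sprintf("PERI_G%04d", peri_counter + seq_len(cfg$periphery_per_term))
        peri_counter <- peri_counter + cfg$periphery_per_term
        id <- sprintf("TERM_B%d_T%02d", b, t)
        terms[[id]] <- c(core, peri)
        descr[id] <- sprintf("planted process %d, variant %d", b, t)
        blocks[id] <- b
      }
    }
    for (f in seq_len(cfg$n_filler_terms)) {
      id <- sprintf("TERM_BG_%02d", f)
      terms[[id]] <- sprintf("BGG_F%d_G%03d", f, seq_len(cfg$filler_term_size))
      descr[id] <- sprintf("background catalogue term %d", f)
    }
    # shuffle term order so downstream order-invariance is exercised
    ord <- sample(length(terms))
    list(collection = annotation_collection(terms[ord], term_names = descr),
         blocks = blocks)
  })
}

#' Reference centrality fixture of the seven crucial Crohn's disease genes
#'
#' The published centrality table this pipeline is modeled on reports, for a
#' 39-gene query set on a 59-node main component, four hubs (GATA3 K=28
#' BC=0.038, IL-7 26/0.007, CD28 26/0.006, CD5 25/0.005) and four bottlenecks
#' (TXN 9/0.069, ETS-1 19/0.042, GATA3 28/0.038, CCR7 23/0.036), with GATA3
#' the only hub-bottleneck. This fixture packages those printed rows padded
#' with 32 synthetic filler query genes (K <= 8, BC <= 0.004, so they can
#' never enter either top-decile list) to restore the reported query-set size
#' of 39. It is a worked-example table, not a reconstruction of the
#' underlying network.
#'
#' @return List: `centrality` (a `CentralityTable` of 39 query rows),
#'   `query_ids`, `crucial` (the seven reported genes), `hubs`,
#'   `bottlenecks` (reported memberships, in reported rank order).
#' @export
reference_centrality_fixture <- function() {
  printed <- data.frame(
    node_id = c("GATA3", "IL-7", "CD28", "CD5", "TXN", "ETS-1", "CCR7"),
    K = c(28L, 26L, 26L, 25L, 9L, 19L, 23L),
    BC = c(0.038, 0.007, 0.006, 0.005, 0.069, 0.042, 0.036),
    stringsAsFactors = FALSE)
  filler <- data.frame(
    node_id = sprintf("QFILL%02d", 1:32),
    K = rep(2:8, length.out = 32),
    BC = round(seq(0.0001, 0.004, length.out = 32), 6),
    stringsAsFactors = FALSE)
  tab <- rbind(printed, filler)
  tab <- data.frame(node_id = tab$node_id, role = "query",
                    K = tab$K, BC = tab$BC, stringsAsFactors = FALSE)
  tab <- tab[order(tab$node_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "component_size") <- 59L
  class(tab) <- c("CentralityTable", "data.frame")
  list(centrality = tab,
       query_ids = tab$node_id,
       crucial = printed$node_id,
       hubs = c("GATA3", "IL-7", "CD28", "CD5"),
       bottlenecks = c("TXN", "ETS-1", "GATA3", "CCR7"))
}

#' Write a complete synthetic study to a directory
#'
#' Generates the expression matrix, sample map, interaction database and GMT
#' file for one seeded synthetic study, plus a `truth.json` with every
#' planted label, so any pipeline stage can be run from files.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named list of file paths plus the truth list.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(cfg)
  db <- simulate_database(cfg, expr$planted$gene_id)
  ann <- simulate_annotations(cfg, c(db$target,
                                     utils::head(db$connectable, 8)))
  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    sample_map = file.path(outdir, "samples.tsv"),
    database = file.path(outdir, "interactions.tsv"),
    gmt = file.path(outdir, "annotations.gmt"),
    truth = file.path(outdir, "truth.json"))
  write_expression(expr$matrix, paths$expression)
  write_sample_groups(expr$groups, paths$sample_map)
  write_database(db$db, paths$database)
  write_gmt(ann$collection, paths$gmt)
  truth <- list(planted_de = expr$planted, target = db$target,
                mapped = db$mapped, connectable = db$connectable,
                isolated = db$isolated, anchors = db$anchors,
                term_blocks = as.list(ann$blocks))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth_data = truth)))
}
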