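#' Per-gene differential expression by Welch t-test
#'
#' For every gene, compares case vs control log2 values with a two-sample
#' Welch (unequal-variance) t-test. The effect is reported as
#' `log2fc = mean(case) - mean(control)` and as a two-sided fold change
#' `fold_change = 2^|log2fc|`, so up- and down-regulated genes are treated
#' symmetrically. p-values are Benjamini-Hochberg adjusted across all tested
#' genes (`q_value`), and significance is flagged with [flag_significant()]
#' using the raw p-value.
#'
#' Degenerate genes: if both groups have zero variance and equal means the
#' p-value is 1 (no evidence); zero variance in both groups with differing
#' means is clamped to p = 1e-300 rather than 0 so the ranking stays
#' well-defined.
#'
#' @param m An [expression_matrix()] (log2 scale).
#' @param g A [sample_groups()] covering every sample in `m`.
#' @param fc_cutoff,p_cutoff Significance thresholds passed to
#'   [flag_significant()] (defaults: fold change strictly above 2, raw p-value
#'   at most 0.05).
#' @return A `DEGTable`: data frame with columns `gene_id`, `log2fc`,
#'   `fold_change`, `p_value`, `q_value`, `significant`, sorted ascending by
#'   `(p_value, gene_id)`; attribute `n_significant`.
#' @export
differential_expression <- function(m, g, fc_cutoff = 2, p_cutoff = 0.05) {
  if (!inherits(g, "SampleGroups")) stop("`g` must be a SampleGroups object",
                                         call. = FALSE)
  x <- unclass(m)
  if (!all(g$sample_id %in% colnames(x)) || !all(colnames(x) %in% g$sample_id)) {
    stop("sample map and matrix sample ids do not match", call. = FALSE)
  }
  case_ids <- g$sample_id[g$group == attr(g, "case")]
  ctrl_ids <- g$sample_id[g$group == attr(g, "control")]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  x1 <- x[, case_ids, drop = FALSE]
  x2 <- x[, ctrl_ids, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  dm <- m1 - m2
  tstat <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- se2 == 0
  p[zero_se & dm == 0] <- 1
  p[zero_se & dm != 0] <- 1e-300
  p <- pmin(pmax(p, 1e-300), 1)
  tab <- data.frame(gene_id = rownames(x),
                    log2fc = dm,
                    fold_change = 2^abs(dm),
                    p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$p_value, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("DEGTable", "data.frame")
  flag_significant(tab, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
}

#' Keep the top-n genes by p-value
#'
#' Returns the first `min(n, nrow)` records in `(p_value, gene_id)` order
#' (ties at the boundary are broken lexicographically by gene id, so the
#' selection is deterministic).
#'
#' @param table A `DEGTable`.
#' @param n Number of genes to keep (default 250).
#' @export
select_top <- function(table, n = 250) {
  stopifnot(n >= 1)
  table <- table[order(table$p_value, table$gene_id), , drop = FALSE]
  out <- utils::head(table, n)
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  attr(out, "n_top") <- n
  flag_significant(out,
                   fc_cutoff = attr(table, "fc_cutoff") %||% 2,
                   p_cutoff = attr(table, "p_cutoff") %||% 0.05)
}

#' Flag significant DEGs
#'
#' A gene is significant iff `fold_change > fc_cutoff` (strict) and
#' `p_value <= p_cutoff` (inclusive). The raw p-value is used for the filter;
#' the BH-adjusted `q_value` is reported alongside for the user. Idempotent.
#'
#' @param table A `DEGTable`.
#' @param fc_cutoff Strict fold-change threshold (default 2).
#' @param p_cutoff Inclusive raw p-value threshold (default 0.05).
#' @export
flag_significant <- function(table, fc_cutoff = 2, p_cutoff = 0.05) {
  table$significant <- table$fold_change > fc_cutoff & table$p_value <= p_cutoff
  attr(table, "n_significant") <- sum(table$significant)
  attr(table, "fc_cutoff") <- fc_cutoff
  attr(table, "p_cutoff") <- p_cutoff
  class(table) <- c("DEGTable", "data.frame")
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a DEG table as tab-separated text
#' @param table A `DEGTable`.
#' @param path Output path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
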