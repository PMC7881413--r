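#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` is a numeric genes x samples matrix of log2-scale
#' expression values with unique gene and sample identifiers. It is the raw
#' input to differential-expression filtering.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames. No missing values are allowed (impute before construction; see
#'   [read_expression()] for the load-time imputation policy).
#' @param log2_transformed Logical flag recording whether the values are on
#'   log2 scale (they should be before any downstream analysis).
#' @return An object of class `ExpressionMatrix`: the matrix with a
#'   `log2_transformed` attribute.
#' @export
expression_matrix <- function(values, log2_transformed = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s) > 0) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) {
    stop("`values` contains missing entries after imputation", call. = FALSE)
  }
  structure(values,
            log2_transformed = isTRUE(log2_transformed),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (series-matrix-like layout: `gene_id<TAB>S1<TAB>S2...`). Blank or `NA`
#' cells are imputed with the gene's row median; genes with more than
#' `max_missing` missing are dropped with a warning. If `log2_if_needed` is
#' `TRUE` and the value range indicates a linear scale (maximum above
#' `linear_scale_max`), all values are `log2(x + 1)`-transformed.
#'
#' @param path Path to a tab-separated file.
#' @param log2_if_needed Auto-detect a linear scale and log2-transform it.
#' @param linear_scale_max Values above this trigger the linear-scale
#'   heuristic (default 50; log2 intensities essentially never exceed it).
#' @param max_missing Maximum tolerated fraction of missing cells per gene
#'   before the gene is dropped (default 0.2).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, log2_if_needed = TRUE,
                            linear_scale_max = 50, max_missing = 0.2) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs a gene id column plus >= 1 sample",
                          call. = FALSE)
  gid <- raw[[1]]
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g) > 0) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  sid <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == "" | cells == "NA"] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = list(gid, sid)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 gid[bad[1, 1]], sid[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  miss_frac <- rowMeans(is.na(vals))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warning(sprintf("dropping %d gene(s) with > %.0f%% missing values: %s",
                    sum(drop), 100 * max_missing,
                    paste(utils::head(gid[drop], 10), collapse = ", ")),
            call. = FALSE)
    vals <- vals[!drop, , drop = FALSE]
  }
  if (anyNA(vals)) {
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- med[idx[, 1]]
  }
  log2_flag <- TRUE
  if (log2_if_needed && max(vals) > linear_scale_max) {
    vals <- log2(vals + 1)
  } else if (!log2_if_needed && max(vals) > linear_scale_max) {
    log2_flag <- FALSE
  }
  expression_matrix(vals, log2_transformed = log2_flag)
}

#' Write an expression matrix as tab-separated text
#'
#' Round-trips with [read_expression()] at full printed precision.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a two-group sample map
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character vector of group labels, same length; exactly two
#'   distinct labels with at least 2 samples each.
#' @param case,control Which label is the case (numerator of the fold change)
#'   and which the control.
#' @return A data frame of class `SampleGroups` with columns `sample_id`,
#'   `group`, and attributes `case` / `control`.
#' @export
sample_groups <- function(sample_id, group, case = "case", control = "control") {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("`sample_id` and `group` lengths differ", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in map", call. = FALSE)
  labs <- sort(unique(group))
  if (!setequal(labs, c(case, control))) {
    stop(sprintf("group labels must be exactly {'%s','%s'}; got {%s}",
                 case, control, paste(labs, collapse = ", ")), call. = FALSE)
  }
  if (any(table(group) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  structure(data.frame(sample_id = sample_id, group = group,
                       stringsAsFactors = FALSE),
            case = case, control = control,
            class = c("SampleGroups", "data.frame"))
}

#' Read a sample map from two-column tab-separated text
#'
#' @inheritParams sample_groups
#' @param path Path to a `sample_id<TAB>group` file with header.
#' @export
read_sample_groups <- function(path, case = "case", control = "control") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_groups(df[[1]], df[[2]], case = case, control = control)
}

#' Write a sample map
#' @param g A [sample_groups()] object.
#' @param path Output path.
#' @export
write_sample_groups <- function(g, path) {
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Between-sample comparability check
#'
#' Profiles are comparable (and a between-group comparison meaningful without
#' further normalization) when the per-sample medians line up, the criterion
#' usually eyeballed on a boxplot. Here it is made explicit: the check passes
#' iff every per-sample median is within `tol` log2 units of the cross-sample
#' median of medians.
#'
#' @param m An [expression_matrix()].
#' @param tol Tolerance in log2 units (default 0.5).
#' @return A list of class `qc_comparability`: `per_sample_median` (named),
#'   `global_median`, `failing_samples`, `pass`.
#' @export
check_comparability <- function(m, tol = 0.5) {
  stopifnot(tol > 0)
  med <- apply(unclass(m), 2, stats::median)
  center <- stats::median(med)
  off <- names(med)[abs(med - center) > tol]
  structure(list(per_sample_median = med, global_median = center,
                 failing_samples = off, pass = length(off) == 0, tol = tol),
            class = "qc_comparability")
}

#' @export
print.qc_comparability <- function(x, ...) {
  cat(sprintf("Comparability check: %s (tol = %.3g log2 units)\n",
              if (x$pass) "PASS" else "FAIL", x$tol))
  cat(sprintf("  global median %.3f; %d sample(s) outside tolerance\n",
              x$global_median, length(x$failing_samples)))
  if (length(x$failing_samples) > 0) {
    cat("  offending:", paste(x$failing_samples, collapse = ", "), "\n")
  }
  invisible(x)
}
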