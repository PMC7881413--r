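#!/usr/bin/env Rscript
# Stage 2: QC and differential expression.
#
# Checks between-sample comparability (per-sample medians within 0.5 log2
# units of the median of medians), runs the per-gene Welch t-test, keeps the
# top 250 genes by p-value and flags the significant DEGs (fold change > 2,
# raw p <= 0.05).

suppressPackageStartupMessages(library(netprio))

study_dir <- "results/study"
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

m <- read_expression(file.path(study_dir, "expression.tsv"))
g <- read_sample_groups(file.path(study_dir, "samples.tsv"))

qc <- check_comparability(m, tol = 0.5)
print(qc)
stopifnot(qc$pass)

deg <- differential_expression(m, g)
top <- select_top(deg, 250)
write_deg_table(top, "results/tables/deg_top250.tsv")

cat(sprintf("genes tested: %d; top selected: %d\n", nrow(deg), nrow(top)))
cat(sprintf("significant DEGs (FC > 2, p <= 0.05): %d\n",
            attr(top, "n_significant")))

truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)
flagged <- top$gene_id[top$significant]
cat(sprintf("planted DE genes recovered: %d/%d; false flags: %d\n",
            sum(truth$planted_de$gene_id %in% flagged),
            nrow(truth$planted_de),
            sum(!flagged %in% truth$planted_de$gene_id)))
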