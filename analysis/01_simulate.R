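#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Draws a 104-patient cohort (binary clinical covariates; Poisson CTC counts
# per phenotype under the configured log-linear model) and a gene-by-cell
# count matrix with epithelial / mesenchymal / immune / ribosomal panel
# structure, ribosomal depression in mesenchymal-like cells, overdispersion
# and dropout. Artifacts land in results/: cohort.csv, cohort_truth.json,
# expression.tsv, cell_truth.csv.

suppressPackageStartupMessages(library(ctcemt))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

cfg <- default_run_config(seed = seed)
res <- run_pipeline(cfg, out_dir = "results", stages = "simulate")

coh <- res$simulate$cohort$cohort
prev <- phenotype_prevalence(coh)
cat(sprintf("cohort: %d patients, %.1f%% CTC-positive (%.1f%% mCTC-only)\n",
            prev$n_patients, prev$pct_positive, prev$pct_mCTC_only))
cat(sprintf("matrix: %d genes x %d cells (classes: %s)\n",
            nrow(res$simulate$expression$counts),
            ncol(res$simulate$expression$counts),
            paste(names(cfg$cells$n_cells_per_class), collapse = "/")))
cat("artifacts written under results/\n")
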