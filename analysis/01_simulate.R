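#!/usr/bin/env Rscript
# Stage 1 — simulate the multi-cancer tumor/normal compendium.
#
# Generates the default synthetic cohort (2,000 genes; BLCA, BRCA, COAD,
# HNSC, LIHC, LUAD; 60 tumor + 30 normal each) with 9 planted signal modules
# and 51 co-expressed null modules, and writes per-type raw-count TSVs, CLS
# phenotype files, the true-module GMT and the truth JSON under
# results/data/. Everything downstream reads these files.

suppressPackageStartupMessages(library(pancansig))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1L]]) else 17L
message("simulate: seed = ", seed)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_cohort_config()
truth <- build_truth(cfg, seed)
cohorts <- simulate_counts(truth, seed + 1L)

for (ct in names(cohorts)) {
  write_expression_matrix(cohorts[[ct]]$counts, file.path(out, paste0(ct, "_counts.tsv")))
  write_cls(cohorts[[ct]]$labels, file.path(out, paste0(ct, "_phenotype.cls")))
  message(sprintf("  %s: %d genes x %d samples (%d tumor / %d normal)",
                  ct, nrow(cohorts[[ct]]$counts), ncol(cohorts[[ct]]$counts),
                  sum(cohorts[[ct]]$labels$class == 1L),
                  sum(cohorts[[ct]]$labels$class == 0L)))
}
write_gmt(true_module_sets(truth), file.path(out, "true_modules.gmt"))
write_truth(truth, file.path(out, "truth.json"))
writeLines(as.character(seed), file.path(out, "seed.txt"))
message("simulate: wrote cohort files to ", out)
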