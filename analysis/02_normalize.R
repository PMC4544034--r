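#!/usr/bin/env Rscript
# Stage 2 — median-of-ratios normalization per cancer type.
#
# Reads the raw-count TSVs written by 01_simulate.R, estimates per-sample
# size factors (geometric-mean reference over genes positive in every
# sample, rescaled to geometric mean 1), and writes normalized expression
# TSVs plus a size-factor table under results/normalized/.

suppressPackageStartupMessages(library(pancansig))
ind <- "results/data"; out <- "results/normalized"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

count_files <- list.files(ind, pattern = "_counts\\.tsv$", full.names = TRUE)
stopifnot(length(count_files) > 0L)

sf_rows <- list()
for (f in count_files) {
  ct <- sub("_counts\\.tsv$", "", basename(f))
  counts <- read_count_matrix(f)
  fac <- estimate_size_factors(counts)
  norm <- normalize_counts(counts, fac)
  write_expression_matrix(round(norm, 4), file.path(out, paste0(ct, "_normalized.tsv")))
  sf_rows[[ct]] <- data.frame(cancer_type = ct, sample_id = names(fac),
                              size_factor = sprintf("%.6f", fac))
  message(sprintf("  %s: size factors in [%.3f, %.3f]", ct, min(fac), max(fac)))
}
write.table(do.call(rbind, sf_rows), file.path(out, "size_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("normalize: wrote normalized matrices to ", out)
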