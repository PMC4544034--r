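#!/usr/bin/env Rscript
# Stage 3 — de-novo co-expression clustering over pooled normal samples.
#
# Pools the log2 normalized expression of all *normal* samples across
# cancer types (tumor status must not shape the clusters), computes Pearson
# similarities between genes, runs affinity propagation with the preference
# set to the 0.98 quantile of the similarities, and size-filters the
# clusters to 15-100 genes. Writes the full and filtered cluster GMTs and a
# summary TSV under results/clusters/.

suppressPackageStartupMessages(library(pancansig))
ind <- "results/normalized"; datad <- "results/data"; out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

norm_files <- list.files(ind, pattern = "_normalized\\.tsv$", full.names = TRUE)
stopifnot(length(norm_files) > 0L)

normal_log <- do.call(cbind, lapply(norm_files, function(f) {
  ct <- sub("_normalized\\.tsv$", "", basename(f))
  mat <- as.matrix(read.delim(f, row.names = 1L, check.names = FALSE))
  lab <- read_cls(file.path(datad, paste0(ct, "_phenotype.cls")))
  log_transform(mat[, lab$class == 0L, drop = FALSE])
}))
message(sprintf("clustering input: %d genes x %d pooled normal samples",
                nrow(normal_log), ncol(normal_log)))

sim <- pearson_similarity(normal_log, drop_zero_variance = TRUE)
pref <- preference_from_quantile(sim, 0.98)
message(sprintf("preference (q = 0.98 similarity quantile): %.4f", pref))

ap <- affinity_propagation(sim, pref)
message(sprintf("affinity propagation: %d clusters, %s after %d iterations",
                ap$n_clusters, if (ap$converged) "converged" else "NOT converged",
                ap$iterations_run))

all_clusters <- clusters_to_collection(ap)
filtered <- filter_gene_sets(all_clusters, 15L, 100L)
write_gmt(all_clusters, file.path(out, "clusters_all.gmt"))
write_gmt(filtered, file.path(out, "clusters_filtered.gmt"))
write.table(
  data.frame(cluster = names(all_clusters), size = lengths(all_clusters),
             exemplar = sub("^exemplar ", "", attr(all_clusters, "description"))),
  file.path(out, "cluster_summary.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
message(sprintf("cluster: %d/%d clusters kept by the 15-100 size filter",
                length(filtered), length(all_clusters)))
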