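#!/usr/bin/env Rscript
# Stage 5 — compact panels and leave-one-out cross-validated classification.
#
# Takes the clusters called cross-cancer in stage 4, extracts the two most
# differentially expressed genes of each (mean |S2N| over the types where
# the cluster is significant), and evaluates the panel by per-type LOOCV
# with a fold-standardized linear SVM. Separately, uses the cluster best
# matching the planted tissue-restricted module to run the tumors-only
# "target tissue vs all other tumors" cohort task.

suppressPackageStartupMessages(library(pancansig))
ind <- "results/normalized"; datad <- "results/data"; out <- "results/signature"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clusters <- read_gmt("results/clusters/clusters_filtered.gmt")
calls <- read.delim("results/association/signature_calls.tsv")
norm_files <- list.files(ind, pattern = "_normalized\\.tsv$", full.names = TRUE)
types <- sub("_normalized\\.tsv$", "", basename(norm_files))

mats <- list(); labs <- list(); rankings <- list()
for (ti in seq_along(types)) {
  ct <- types[ti]
  mats[[ct]] <- as.matrix(read.delim(norm_files[ti], row.names = 1L, check.names = FALSE))
  cls <- read_cls(file.path(datad, paste0(ct, "_phenotype.cls")))
  labs[[ct]] <- phenotype_labels(colnames(mats[[ct]]), cls$class, cls$class_names)
  rankings[[ct]] <- signal2noise(mats[[ct]], labs[[ct]])
}

cross <- calls$set_name[calls$category == "cross-cancer"]
stopifnot(length(cross) > 0L)
sig_types <- lapply(cross, function(s) {
  strsplit(calls$significant_types[calls$set_name == s], ",")[[1L]]
})
names(sig_types) <- cross
panel <- extract_signature(clusters[cross], rankings, sig_types, k = 2L)
pan_out <- panel
pan_out$extraction_score <- sprintf("%.4f", pan_out$extraction_score)
write.table(pan_out, file.path(out, "panel.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("panel: %d genes from %d cross-cancer clusters",
                nrow(panel), length(cross)))

loocv_rows <- lapply(types, function(ct) {
  rep <- loocv(log_transform(mats[[ct]][panel$gene_id, , drop = FALSE]), labs[[ct]])
  message(sprintf("  %s: LOOCV accuracy %.2f%% (%d/%d)",
                  ct, 100 * rep$accuracy, rep$n_correct, rep$n_samples))
  data.frame(cancer_type = ct, n_samples = rep$n_samples,
             n_correct = rep$n_correct,
             accuracy_pct = sprintf("%.2f", 100 * rep$accuracy))
})
write.table(do.call(rbind, loocv_rows), file.path(out, "loocv_per_type.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# tissue-restricted task: pick the filtered cluster best matching the
# planted tissue module, then separate that tissue's tumors from all others
truth_sets <- read_gmt(file.path(datad, "true_modules.gmt"))
match_tab <- match_sets_to_truth(clusters, truth_sets)
tiss_row <- match_tab[match_tab$module == "TISSUE_LUAD", ]
feats <- lapply(mats, log_transform)
task <- build_cohort_task(feats, labs, positive_types = "LUAD",
                          sample_filter = "tumor")
tiss <- loocv(task$features[clusters[[tiss_row$matched_set]], , drop = FALSE],
              task$labels)
message(sprintf("tissue task (%s ~ %s, Jaccard %.2f): accuracy %.2f%% (%d/%d tumors)",
                tiss_row$matched_set, tiss_row$module, tiss_row$jaccard,
                100 * tiss$accuracy, tiss$n_correct, tiss$n_samples))
write.table(
  data.frame(task = "LUAD_tumors_vs_other_tumors",
             cluster = tiss_row$matched_set, module = tiss_row$module,
             jaccard = sprintf("%.3f", tiss_row$jaccard),
             n_samples = tiss$n_samples, n_correct = tiss$n_correct,
             accuracy_pct = sprintf("%.2f", 100 * tiss$accuracy)),
  file.path(out, "tissue_task.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
message("signature: wrote tables to ", out)
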