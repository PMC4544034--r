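#!/usr/bin/env Rscript
# Stage 4 — per-cancer gene-set association and signature calling.
#
# For every cancer type: rank genes by signal-to-noise (tumor vs normal) on
# the normalized linear expression, score every size-filtered cluster with
# the weighted-KS enrichment statistic, build the phenotype-permutation null
# (1,000 label shuffles), and attach NES, nominal p and sign-separated FDR.
# Gene sets with FDR < 0.15 in >= 4 types are called cross-cancer, in
# exactly one type cancer-specific. Also writes the top-3% |S2N| overlap
# matrix between cancer types (the "how similar are DE programs" view).

suppressPackageStartupMessages(library(pancansig))
seed <- as.integer(readLines("results/data/seed.txt"))
ind <- "results/normalized"; datad <- "results/data"; out <- "results/association"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clusters <- read_gmt("results/clusters/clusters_filtered.gmt")
norm_files <- list.files(ind, pattern = "_normalized\\.tsv$", full.names = TRUE)
types <- sub("_normalized\\.tsv$", "", basename(norm_files))

rankings <- list(); assoc <- list()
for (ti in seq_along(types)) {
  ct <- types[ti]
  mat <- as.matrix(read.delim(norm_files[ti], row.names = 1L, check.names = FALSE))
  cls <- read_cls(file.path(datad, paste0(ct, "_phenotype.cls")))
  lab <- phenotype_labels(colnames(mat), cls$class, cls$class_names)
  rankings[[ct]] <- signal2noise(mat, lab)
  res <- associate_gene_sets(mat, lab, clusters, n_perm = 1000L,
                             seed = seed + 100L + ti)
  res$cancer_type <- ct
  assoc[[ct]] <- res
  message(sprintf("  %s: %d/%d gene sets at FDR < 0.15",
                  ct, sum(res$FDR < 0.15), nrow(res)))
}

tab <- do.call(rbind, assoc); rownames(tab) <- NULL
num <- vapply(tab, is.numeric, logical(1))
out_tab <- tab; out_tab[num] <- lapply(tab[num], function(x) sprintf("%.6g", x))
write.table(out_tab, file.path(out, "association.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

calls <- classify_signatures(tab, fdr_threshold = 0.15, cross_min_types = 4L)
write.table(calls, file.path(out, "signature_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("association: %d cross-cancer, %d cancer-specific, %d shared-2-3 of %d sets",
                sum(calls$category == "cross-cancer"),
                sum(calls$category == "cancer-specific"),
                sum(calls$category == "shared-2-3"), nrow(calls)))

ovl <- top_fraction_overlap(rankings, fraction = 0.03)
write.table(data.frame(cancer_type = rownames(ovl), round(ovl, 2),
                       check.names = FALSE),
            file.path(out, "top3pct_gene_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("association: wrote tables to ", out)
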