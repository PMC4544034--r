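#' Run the full signature-discovery pipeline on a synthetic cohort
#'
#' Simulates a multi-cancer tumor/normal cohort, normalizes each cancer type
#' by median-of-ratios size factors, clusters genes by affinity propagation
#' on Pearson similarities over the pooled normal samples (log2 scale),
#' size-filters the clusters, tests every surviving gene set per cancer type
#' with the signal-to-noise weighted-KS permutation statistic, calls
#' cross-cancer and cancer-specific signatures, extracts a top-`k`-per-cluster
#' panel from the cross-cancer sets and evaluates it by per-type LOOCV. All
#' randomness derives from `seed`; outputs written under `out_dir` are
#' byte-reproducible.
#'
#' @param config A [cohort_config()]; default [default_cohort_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory for TSV/CLS/GMT/JSON outputs.
#' @param n_perm Permutations per cancer type.
#' @param q Preference quantile for affinity propagation.
#' @param fdr_threshold Significance threshold for signature calling.
#' @param cross_min_types Minimum significant types for a cross-cancer call.
#' @param k Panel genes per cluster.
#' @param min_size,max_size Gene-set size filter bounds.
#' @return List: `truth`, `cohorts`, `normalized`, `clusters` (filtered
#'   [gene_set_collection()]), `assignment`, `association` (stacked per-type
#'   results), `signatures` (classification), `panel`, `loocv` (per-type
#'   accuracies), `rankings`.
#' @export
run_cohort_pipeline <- function(config = default_cohort_config(), seed = 17L,
                                out_dir = NULL, n_perm = 1000L, q = 0.98,
                                fdr_threshold = 0.15, cross_min_types = 4L,
                                k = 2L, min_size = 15L, max_size = 100L) {
  seed <- as.integer(seed)
  truth <- build_truth(config, seed)
  cohorts <- simulate_counts(truth, seed + 1L)
  types <- config$cancer_types

  normalized <- lapply(cohorts, function(co) {
    fac <- estimate_size_factors(co$counts)
    normalize_counts(co$counts, fac)
  })

  # clustering input: log2 normalized expression of pooled normal samples
  normal_log <- do.call(cbind, lapply(types, function(ct) {
    lab <- cohorts[[ct]]$labels
    log_transform(normalized[[ct]][, lab$sample_ids[lab$class == 0L], drop = FALSE])
  }))
  sim <- pearson_similarity(normal_log, drop_zero_variance = TRUE)
  pref <- preference_from_quantile(sim, q)
  assignment <- affinity_propagation(sim, pref)
  all_clusters <- clusters_to_collection(assignment)
  clusters <- filter_gene_sets(all_clusters, min_size, max_size)

  rankings <- list(); assoc <- list()
  for (ti in seq_along(types)) {
    ct <- types[ti]
    lab <- cohorts[[ct]]$labels
    rankings[[ct]] <- signal2noise(normalized[[ct]], lab)
    if (length(clusters) == 0L) next
    res <- associate_gene_sets(normalized[[ct]], lab, clusters,
                               n_perm = n_perm, seed = seed + 100L + ti)
    res$cancer_type <- ct
    assoc[[ct]] <- res
  }
  if (length(assoc) > 0L) {
    association <- do.call(rbind, assoc)
    rownames(association) <- NULL
    signatures <- classify_signatures(association, fdr_threshold, cross_min_types)
  } else {
    message("no gene sets survived the size filter; association stage skipped")
    association <- NULL
    signatures <- data.frame(set_name = character(0),
                             n_significant_types = integer(0),
                             significant_types = character(0),
                             category = character(0))
  }

  cross_sets <- signatures$set_name[signatures$category == "cross-cancer"]
  panel <- NULL; loocv_acc <- NULL
  if (length(cross_sets) > 0L) {
    sig_types <- lapply(cross_sets, function(s) {
      strsplit(signatures$significant_types[signatures$set_name == s], ",")[[1L]]
    })
    names(sig_types) <- cross_sets
    cross_coll <- gene_set_collection(unclass(clusters)[cross_sets])
    panel <- extract_signature(cross_coll, rankings, sig_types, k = k)
    loocv_acc <- vapply(types, function(ct) {
      feats <- log_transform(normalized[[ct]][panel$gene_id, , drop = FALSE])
      loocv(feats, cohorts[[ct]]$labels)$accuracy
    }, numeric(1))
  }

  result <- list(truth = truth, cohorts = cohorts, normalized = normalized,
                 clusters = clusters, assignment = assignment,
                 association = association, signatures = signatures,
                 panel = panel, loocv = loocv_acc, rankings = rankings)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write the text outputs of a pipeline run
#'
#' Per-cancer count TSV and CLS files, the true-module GMT and truth JSON,
#' the filtered cluster GMT, the association table, signature calls, the
#' panel and LOOCV accuracies — all plain text with fixed numeric formatting
#' so identical runs are byte-identical.
#'
#' @param result A [run_cohort_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in names(result$cohorts)) {
    write_expression_matrix(result$cohorts[[ct]]$counts,
                            file.path(out_dir, paste0(ct, "_counts.tsv")))
    write_cls(result$cohorts[[ct]]$labels,
              file.path(out_dir, paste0(ct, "_phenotype.cls")))
  }
  write_truth(result$truth, file.path(out_dir, "truth.json"))
  write_gmt(true_module_sets(result$truth),
            file.path(out_dir, "true_modules.gmt"))
  if (length(result$clusters) > 0L) {
    write_gmt(result$clusters, file.path(out_dir, "clusters_filtered.gmt"))
  }
  if (!is.null(result$association)) {
    assoc <- result$association
    num <- vapply(assoc, is.numeric, logical(1))
    assoc[num] <- lapply(assoc[num], function(x) sprintf("%.6g", x))
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$signatures, file.path(out_dir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$panel)) {
    pan <- result$panel
    pan$extraction_score <- sprintf("%.6g", pan$extraction_score)
    utils::write.table(pan, file.path(out_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$loocv)) {
    utils::write.table(
      data.frame(cancer_type = names(result$loocv),
                 accuracy = sprintf("%.6g", result$loocv)),
      file.path(out_dir, "loocv.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(out_dir)
}

#' Match recovered gene sets to planted modules
#'
#' For every planted module, finds the recovered set with the highest
#' Jaccard index against it.
#'
#' @param recovered A [gene_set_collection()] (e.g. filtered clusters).
#' @param truth_sets A [gene_set_collection()] of planted modules.
#' @return data.frame: `module`, `matched_set`, `jaccard`.
#' @export
match_sets_to_truth <- function(recovered, truth_sets) {
  stopifnot(inherits(recovered, "gene_set_collection"),
            inherits(truth_sets, "gene_set_collection"))
  res <- lapply(names(truth_sets), function(m) {
    tg <- truth_sets[[m]]
    jac <- vapply(recovered, function(rg) {
      length(intersect(tg, rg)) / length(union(tg, rg))
    }, numeric(1))
    best <- if (length(jac)) which.max(jac) else NA_integer_
    data.frame(module = m,
               matched_set = if (length(jac)) names(recovered)[best] else NA_character_,
               jaccard = if (length(jac)) unname(jac[best]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
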