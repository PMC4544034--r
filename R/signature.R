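#' Extract a compact gene panel from significant clusters
#'
#' For every cluster, member genes are ranked by their absolute
#' signal-to-noise score aggregated (unweighted mean) over the cancer types
#' in which that cluster is significant, and the top `k` are taken (fewer if
#' the cluster is smaller). The panel is deduplicated preserving first
#' occurrence. Seven significant clusters at the default `k = 2` yield a
#' 14-gene panel.
#'
#' @param clusters A [gene_set_collection()] of the significant clusters.
#' @param rankings Named list of ranked gene lists (per cancer type), as
#'   from [signal2noise()].
#' @param sig_types Optional named list mapping cluster name to the cancer
#'   types where it is significant; defaults to aggregating over all
#'   supplied rankings.
#' @param k Genes to take per cluster (default 2).
#' @return A data.frame: `gene_id`, `source_cluster`, `extraction_score`.
#' @export
extract_signature <- function(clusters, rankings, sig_types = NULL, k = 2L) {
  stopifnot(inherits(clusters, "gene_set_collection"), length(clusters) >= 1L,
            is.list(rankings), length(rankings) >= 1L, k >= 1L)
  score_of <- lapply(rankings, function(r) {
    stats::setNames(abs(r$score), r$gene_id)
  })
  panel <- list()
  for (nm in names(clusters)) {
    genes <- clusters[[nm]]
    types <- if (!is.null(sig_types) && !is.null(sig_types[[nm]]) &&
                 length(sig_types[[nm]]) > 0L) sig_types[[nm]] else names(rankings)
    types <- intersect(types, names(rankings))
    if (length(types) == 0L) stop("cluster '", nm, "' has no usable rankings")
    per_type <- vapply(types, function(ct) {
      score_of[[ct]][genes]
    }, numeric(length(genes)))
    agg <- rowMeans(matrix(per_type, nrow = length(genes)))
    names(agg) <- genes
    agg <- agg[!is.na(agg)]
    if (length(agg) == 0L) {
      stop("cluster '", nm, "' has no genes present in the rankings")
    }
    take <- min(k, length(agg))
    if (take < k) {
      message(sprintf("cluster '%s' contributes %d gene(s) (smaller than k = %d)",
                      nm, take, k))
    }
    top <- names(sort(agg, decreasing = TRUE))[seq_len(take)]
    panel[[nm]] <- data.frame(gene_id = top, source_cluster = nm,
                              extraction_score = unname(agg[top]),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, panel)
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated linear SVM classification
#'
#' For every sample: z-score each feature gene using the mean and standard
#' deviation of the *training* fold only (no leakage), train a soft-margin
#' linear support-vector machine (cost `C`) on the remaining samples, and
#' predict the held-out sample. Accuracy is the proportion of correct
#' predictions.
#'
#' @param features Expression matrix restricted to panel genes
#'   (genes x samples).
#' @param labels [phenotype_labels()] over the samples.
#' @param C Soft-margin cost (default 1).
#' @param standardize One of "fold" (z-score fit on each training fold; the
#'   default) or "none".
#' @return A `loocv_report` list: `n_samples`, `n_correct`, `accuracy`,
#'   `predicted`, `truth`.
#' @export
loocv <- function(features, labels, C = 1, standardize = c("fold", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(is.matrix(features), inherits(labels, "phenotype_labels"),
            setequal(colnames(features), labels$sample_ids))
  cls <- labels$class[match(colnames(features), labels$sample_ids)]
  if (sum(cls == 0L) < 2L || sum(cls == 1L) < 2L) {
    stop("LOOCV requires at least 2 samples per class")
  }
  x <- t(features)  # samples x genes
  n <- nrow(x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- cls[-i]
    xte <- x[i, , drop = FALSE]
    if (length(unique(ytr)) < 2L) stop("a leave-one-out fold leaves a class empty")
    if (standardize == "fold") {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, `/`)
      xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, `/`)
    }
    fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0L, 1L)),
                      kernel = "linear", cost = C, scale = FALSE)
    pred[i] <- as.integer(as.character(stats::predict(fit, xte)))
  }
  n_correct <- sum(pred == cls)
  structure(list(n_samples = n, n_correct = n_correct,
                 accuracy = n_correct / n,
                 predicted = stats::setNames(pred, colnames(features)),
                 truth = stats::setNames(cls, colnames(features))),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("loocv_report: %d/%d correct, accuracy %.4f\n",
              x$n_correct, x$n_samples, x$accuracy))
  invisible(x)
}

#' Assemble a cross-cohort classification task
#'
#' Concatenates samples across per-cancer expression matrices (intersecting
#' their gene universes) and labels them by cohort membership: samples from
#' `positive_types` become class 1. With `sample_filter = "tumor"` only
#' tumor samples enter (the lung-vs-non-lung style task); with `"all"` every
#' sample does.
#'
#' @param cohorts Named list of expression matrices (genes x samples), one
#'   per cancer type.
#' @param phenos Named list of [phenotype_labels()] matching `cohorts`.
#' @param positive_types Cancer types forming class 1; must be a non-empty
#'   strict subset of the cohort names.
#' @param sample_filter "tumor" or "all".
#' @return List with `features` (genes x samples matrix) and `labels`
#'   ([phenotype_labels()] with classes positive/negative cohort).
#' @export
build_cohort_task <- function(cohorts, phenos, positive_types,
                              sample_filter = c("tumor", "all")) {
  sample_filter <- match.arg(sample_filter)
  stopifnot(is.list(cohorts), length(cohorts) >= 2L,
            setequal(names(cohorts), names(phenos)))
  if (length(positive_types) == 0L ||
      !all(positive_types %in% names(cohorts)) ||
      length(setdiff(names(cohorts), positive_types)) == 0L) {
    stop("positive_types must be a non-empty strict subset of the cohort types")
  }
  genes <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(genes) == 0L) stop("cohorts share no gene identifiers")
  blocks <- list(); cls <- integer(0); ids <- character(0)
  for (ct in names(cohorts)) {
    keep <- phenos[[ct]]$sample_ids
    if (sample_filter == "tumor") keep <- keep[phenos[[ct]]$class == 1L]
    if (length(keep) == 0L) next
    blocks[[ct]] <- cohorts[[ct]][genes, keep, drop = FALSE]
    cls <- c(cls, rep(as.integer(ct %in% positive_types), length(keep)))
    ids <- c(ids, keep)
  }
  features <- do.call(cbind, blocks)
  colnames(features) <- ids
  list(features = features,
       labels = phenotype_labels(ids, cls,
                                 class_names = c("negative_cohort", "positive_cohort")))
}
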