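#' Signal-to-noise gene ranking between two phenotype classes
#'
#' `S2N_g = (mu_1 - mu_0) / (sd_1 + sd_0)` with class 1 (tumor) first, using
#' sample standard deviations and the GSEA-style variance floor
#' `sd <- max(sd, 0.2 * |mu|)`, and `sd <- 0.2` when `mu = 0`. Genes are
#' returned sorted by descending score, ties broken by gene id.
#'
#' @param expr Expression matrix (genes x samples), linear scale.
#' @param labels [phenotype_labels()] covering the samples.
#' @return A data.frame (`gene_id`, `score`) sorted by descending score.
#' @export
signal2noise <- function(expr, labels) {
  stopifnot(is.matrix(expr), inherits(labels, "phenotype_labels"),
            setequal(colnames(expr), labels$sample_ids))
  cls <- labels$class[match(colnames(expr), labels$sample_ids)]
  if (sum(cls == 0L) < 2L || sum(cls == 1L) < 2L) {
    stop("signal2noise requires at least 2 samples in each class")
  }
  score <- .s2n_scores(expr, cls == 1L)
  ord <- order(-score, rownames(expr))
  data.frame(gene_id = rownames(expr)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

# vectorized S2N for a logical class-1 indicator; returns per-row scores
.s2n_scores <- function(expr, is1) {
  m1 <- rowMeans(expr[, is1, drop = FALSE])
  m0 <- rowMeans(expr[, !is1, drop = FALSE])
  s1 <- apply(expr[, is1, drop = FALSE], 1L, stats::sd)
  s0 <- apply(expr[, !is1, drop = FALSE], 1L, stats::sd)
  (m1 - m0) / (.floor_sd(s1, m1) + .floor_sd(s0, m0))
}

.floor_sd <- function(s, m) {
  fl <- ifelse(m == 0, 0.2, 0.2 * abs(m))
  pmax(s, fl)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running sum over a ranked gene list: at each rank the sum rises
#' by `|score|^p / sum_hits |score|^p` for gene-set members and falls by
#' `1 / (N - N_hit)` for non-members; the enrichment score is the signed
#' maximum deviation from zero. Set members absent from the ranking are
#' ignored (with a message).
#'
#' @param ranking A ranked gene list as returned by [signal2noise()].
#' @param geneset Character vector of member gene ids.
#' @param p Weight exponent (default 1, the weighted form).
#' @return The enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranking, geneset, p = 1) {
  stopifnot(is.data.frame(ranking), all(c("gene_id", "score") %in% names(ranking)))
  hit <- ranking$gene_id %in% geneset
  n_absent <- length(setdiff(geneset, ranking$gene_id))
  if (n_absent > 0L) {
    message(sprintf("%d gene-set members absent from the ranking were ignored", n_absent))
  }
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no members in the ranking")
  if (n_hit == nrow(ranking)) stop("gene set covers every ranked gene; no misses to walk")
  .es_from_positions(which(hit), abs(ranking$score[hit])^p, nrow(ranking))
}

# ES from sorted hit positions and their weights; O(N_hit). The running sum's
# maximum lies at a hit position and its minimum just before a hit position,
# so only those 2*N_hit candidates are examined.
.es_from_positions <- function(pos, w, n) {
  n_hit <- length(pos)
  sw <- sum(w)
  p_hit <- if (sw > 0) cumsum(w) / sw else cumsum(rep(1 / n_hit, n_hit))
  miss_before <- (pos - seq_len(n_hit)) / (n - n_hit)
  dev_at <- p_hit - miss_before                      # just after each hit
  dev_pre <- c(0, p_hit[-n_hit]) - miss_before       # just before each hit
  hi <- max(dev_at)
  lo <- min(dev_pre, 0)
  # positive deviation wins exact magnitude ties; the tolerance keeps the
  # rule stable when both extremes are the same rational number computed
  # along different floating-point paths
  if (hi + lo >= -1e-12) hi else lo
}

#' Phenotype-permutation null enrichment scores
#'
#' Shuffles the class labels over samples `n_perm` times; for each
#' permutation recomputes the signal-to-noise ranking and the weighted-KS
#' enrichment score of every gene set. Label (phenotype) permutation is used
#' rather than gene permutation because co-expressed sets make gene
#' permutation anti-conservative.
#'
#' @param expr Expression matrix (genes x samples), linear scale.
#' @param labels [phenotype_labels()].
#' @param genesets A [gene_set_collection()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param p Weight exponent for the enrichment score.
#' @return Matrix of null enrichment scores, sets x permutations.
#' @export
permutation_null <- function(expr, labels, genesets, n_perm = 1000L, seed = 17L,
                             p = 1) {
  stopifnot(is.matrix(expr), inherits(labels, "phenotype_labels"),
            inherits(genesets, "gene_set_collection"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  cls <- labels$class[match(colnames(expr), labels$sample_ids)]
  n1 <- sum(cls == 1L); n0 <- sum(cls == 0L)
  if (n1 < 2L || n0 < 2L) stop("both classes need at least 2 samples")
  n_s <- length(cls)
  if (n_perm > choose(n_s, n1)) {
    warning("n_perm exceeds the number of distinct label permutations; null values will repeat")
  }
  local_seed(seed)
  perm_ind <- matrix(FALSE, n_s, n_perm)
  for (b in seq_len(n_perm)) {
    perm_ind[sample.int(n_s, n1), b] <- TRUE  # class-1 membership per permutation
  }
  scores <- .s2n_scores_multi(expr, perm_ind)
  .es_matrix(scores, rownames(expr), genesets, p)
}

# S2N for many class-1 indicator columns at once (samples x B logical matrix);
# returns genes x B score matrix.
.s2n_scores_multi <- function(expr, ind) {
  mode(ind) <- "numeric"
  n1 <- colSums(ind); n0 <- nrow(ind) - n1
  e1 <- expr %*% ind
  e0 <- rowSums(expr) - e1
  q1 <- (expr^2) %*% ind
  q0 <- rowSums(expr^2) - q1
  m1 <- sweep(e1, 2L, n1, `/`)
  m0 <- sweep(e0, 2L, n0, `/`)
  v1 <- sweep(q1 - sweep(m1^2, 2L, n1, `*`), 2L, n1 - 1, `/`)
  v0 <- sweep(q0 - sweep(m0^2, 2L, n0, `*`), 2L, n0 - 1, `/`)
  s1 <- sqrt(pmax(v1, 0)); s0 <- sqrt(pmax(v0, 0))
  (m1 - m0) / (.floor_sd(s1, m1) + .floor_sd(s0, m0))
}

# ES of every set for every column of a genes x B score matrix
.es_matrix <- function(scores, gene_ids, genesets, p = 1) {
  g <- nrow(scores); b <- ncol(scores)
  set_idx <- lapply(genesets, function(gs) {
    idx <- match(gs, gene_ids)
    idx[!is.na(idx)]
  })
  for (nm in names(set_idx)) {
    if (length(set_idx[[nm]]) == 0L) stop("gene set '", nm, "' has no members in the expression matrix")
    if (length(set_idx[[nm]]) == g) stop("gene set '", nm, "' covers every gene")
  }
  out <- matrix(NA_real_, length(genesets), b,
                dimnames = list(names(genesets), NULL))
  ids_rank <- order(gene_ids)  # lexicographic tiebreak baked into ordering key
  for (col in seq_len(b)) {
    sc <- scores[, col]
    ord <- order(-sc, gene_ids)
    rank_of <- integer(g)
    rank_of[ord] <- seq_len(g)
    w_abs <- abs(sc)^p
    for (si in seq_along(set_idx)) {
      idx <- set_idx[[si]]
      pos <- rank_of[idx]
      o <- order(pos)
      out[si, col] <- .es_from_positions(pos[o], w_abs[idx][o], g)
    }
  }
  out
}

#' Observed enrichment scores for a collection of gene sets
#'
#' @param expr Expression matrix (genes x samples), linear scale.
#' @param labels [phenotype_labels()].
#' @param genesets A [gene_set_collection()].
#' @param p Weight exponent.
#' @return Named numeric vector of enrichment scores.
#' @export
observed_es <- function(expr, labels, genesets, p = 1) {
  cls <- labels$class[match(colnames(expr), labels$sample_ids)]
  scores <- .s2n_scores(expr, cls == 1L)
  drop(.es_matrix(matrix(scores, ncol = 1), rownames(expr), genesets, p))
}

#' Normalize enrichment scores and attach permutation p-values and FDR
#'
#' Sign-separated GSEA procedure: `NES = ES / mean(|same-sign null ES|)`;
#' nominal `p = (1 + #same-sign nulls at least as extreme) / (1 + #same-sign
#' nulls)`; FDR(q) of a set compares the fraction of pooled null NES at least
#' as extreme (same sign) with the fraction of observed NES at least as
#' extreme, capped at 1, then forced monotone non-increasing in `|NES|`
#' within each sign. A set with no same-sign null values gets `p = 1`,
#' `FDR = 1` and is flagged.
#'
#' @param observed Named vector of observed enrichment scores.
#' @param null_es Null score matrix (sets x permutations) from
#'   [permutation_null()], rows matching `observed`.
#' @param genesets Optional [gene_set_collection()] supplying set sizes.
#' @return A data.frame: `set_name`, `size`, `ES`, `NES`, `p_nominal`,
#'   `FDR`, `flagged`.
#' @export
score_sets <- function(observed, null_es, genesets = NULL) {
  stopifnot(is.matrix(null_es), length(observed) == nrow(null_es),
            all(names(observed) == rownames(null_es)))
  n_sets <- length(observed)
  nes <- p_nom <- rep(NA_real_, n_sets)
  flagged <- rep(FALSE, n_sets)
  null_nes <- matrix(NA_real_, n_sets, ncol(null_es))
  for (i in seq_len(n_sets)) {
    es <- observed[i]
    nulls <- null_es[i, ]
    same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    if (length(same) == 0L || mean(abs(same)) == 0) {
      p_nom[i] <- 1; flagged[i] <- TRUE
      next
    }
    p_nom[i] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes[i] <- es / mean(abs(same))
    # normalize this set's nulls by their own sign-specific means for pooling
    pos <- nulls >= 0
    mp <- mean(nulls[pos]); mn <- mean(abs(nulls[!pos]))
    nn <- nulls
    if (any(pos) && mp > 0) nn[pos] <- nulls[pos] / mp
    if (any(!pos) && mn > 0) nn[!pos] <- nulls[!pos] / mn
    null_nes[i, ] <- nn
  }
  pooled <- null_nes[is.finite(null_nes)]
  fdr <- rep(1, n_sets)
  obs_ok <- is.finite(nes)
  for (i in seq_len(n_sets)) {
    if (!obs_ok[i]) next
    if (nes[i] >= 0) {
      null_frac <- if (sum(pooled >= 0) > 0) sum(pooled >= nes[i]) / sum(pooled >= 0) else 0
      obs_frac <- sum(nes[obs_ok] >= nes[i]) / max(1L, sum(nes[obs_ok] >= 0))
    } else {
      null_frac <- if (sum(pooled < 0) > 0) sum(pooled <= nes[i]) / sum(pooled < 0) else 0
      obs_frac <- sum(nes[obs_ok] <= nes[i]) / max(1L, sum(nes[obs_ok] < 0))
    }
    fdr[i] <- min(1, if (obs_frac > 0) null_frac / obs_frac else 1)
  }
  # running-minimum: FDR must not rise as |NES| grows, within each sign
  for (sgn in c(1, -1)) {
    sel <- which(obs_ok & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(sel) > 1L) {
      ord <- sel[order(abs(nes[sel]))]
      fdr[ord] <- cummin(fdr[ord])
    }
  }
  sizes <- if (!is.null(genesets)) lengths(genesets)[names(observed)] else rep(NA_integer_, n_sets)
  data.frame(set_name = names(observed), size = unname(sizes),
             ES = unname(observed), NES = unname(nes),
             p_nominal = unname(p_nom), FDR = unname(fdr),
             flagged = unname(flagged),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-set association analysis for one cancer type
#'
#' Convenience wrapper: observed enrichment scores, phenotype-permutation
#' null and [score_sets()] in one call.
#'
#' @inheritParams permutation_null
#' @return A [score_sets()] data.frame.
#' @export
associate_gene_sets <- function(expr, labels, genesets, n_perm = 1000L,
                                seed = 17L, p = 1) {
  obs <- observed_es(expr, labels, genesets, p = p)
  nulls <- permutation_null(expr, labels, genesets, n_perm = n_perm,
                            seed = seed, p = p)
  score_sets(obs, nulls, genesets)
}

#' Call cross-cancer and cancer-specific signatures
#'
#' Counts, for every gene set, the cancer types where its FDR falls below
#' the threshold: at least `cross_min_types` significant types makes a
#' cross-cancer signature, exactly one a cancer-specific one, two to three
#' "shared-2-3", and none "not-significant".
#'
#' @param table data.frame with columns `set_name`, `cancer_type`, `FDR`
#'   (one row per set and type, e.g. stacked [associate_gene_sets()] output).
#' @param fdr_threshold Significance threshold (default 0.15).
#' @param cross_min_types Minimum significant types for a cross-cancer call.
#' @return data.frame: `set_name`, `n_significant_types`,
#'   `significant_types` (comma-joined), `category`.
#' @export
classify_signatures <- function(table, fdr_threshold = 0.15,
                                cross_min_types = 4L) {
  stopifnot(all(c("set_name", "cancer_type", "FDR") %in% names(table)),
            length(unique(table$cancer_type)) >= 1L)
  sets <- unique(table$set_name)
  res <- lapply(sets, function(s) {
    sub <- table[table$set_name == s, ]
    sig <- sort(unique(sub$cancer_type[sub$FDR < fdr_threshold]))
    k <- length(sig)
    category <- if (k >= cross_min_types) "cross-cancer"
                else if (k == 1L) "cancer-specific"
                else if (k >= 2L) "shared-2-3"
                else "not-significant"
    data.frame(set_name = s, n_significant_types = k,
               significant_types = paste(sig, collapse = ","),
               category = category, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise overlap of top-ranked genes between cancer types
#'
#' For each cancer type the top `floor(fraction * G)` genes by absolute
#' score (minimum 1) are taken; entry (a, b) is the percentage of those top
#' genes shared between types a and b.
#'
#' @param rankings Named list of ranked gene lists (as from
#'   [signal2noise()]), all over the same gene universe.
#' @param fraction Top fraction in (0, 1]; default 0.03.
#' @return Symmetric percentage matrix with 100 on the diagonal.
#' @export
top_fraction_overlap <- function(rankings, fraction = 0.03) {
  stopifnot(is.list(rankings), length(rankings) >= 1L)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  universe <- sort(rankings[[1L]]$gene_id)
  for (r in rankings) {
    if (!identical(sort(r$gene_id), universe)) {
      stop("all rankings must cover the same gene universe")
    }
  }
  g <- length(universe)
  m <- max(1L, floor(fraction * g))
  tops <- lapply(rankings, function(r) {
    ord <- order(-abs(r$score), r$gene_id)
    r$gene_id[ord[seq_len(m)]]
  })
  k <- length(tops)
  out <- matrix(100, k, k, dimnames = list(names(rankings), names(rankings)))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        v <- length(intersect(tops[[i]], tops[[j]])) / m * 100
        out[i, j] <- out[j, i] <- v
      }
    }
  }
  out
}
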