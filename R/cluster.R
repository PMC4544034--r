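#' Pearson similarity matrix between gene expression profiles
#'
#' Computes pairwise Pearson correlations of gene profiles over a sample
#' subset (typically all normal samples pooled across cancer types, so that
#' clusters reflect co-regulation rather than tumor status). The diagonal is
#' left as NA; it is later set to the shared preference.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sample_subset Sample ids to use (default: all columns).
#' @param drop_zero_variance If TRUE, genes with zero variance over the
#'   subset are dropped with a message; if FALSE they raise an error.
#' @return Similarity matrix with gene dimnames and NA diagonal.
#' @export
pearson_similarity <- function(expr, sample_subset = colnames(expr),
                               drop_zero_variance = FALSE) {
  stopifnot(is.matrix(expr), length(sample_subset) >= 3L,
            all(sample_subset %in% colnames(expr)))
  x <- expr[, sample_subset, drop = FALSE]
  v <- apply(x, 1L, stats::var)
  flat <- v == 0 | !is.finite(v)
  if (any(flat)) {
    if (!drop_zero_variance) {
      stop("genes with zero variance over the sample subset: ",
           paste(utils::head(rownames(x)[flat], 10L), collapse = ", "),
           if (sum(flat) > 10L) sprintf(" (and %d more)", sum(flat) - 10L))
    }
    message(sprintf("dropping %d zero-variance genes before similarity", sum(flat)))
    x <- x[!flat, , drop = FALSE]
  }
  s <- stats::cor(t(x))
  diag(s) <- NA_real_
  s
}

#' Preference from a quantile of the input similarities
#'
#' Returns the q-quantile (linear interpolation on the sorted values) of the
#' off-diagonal similarities. Used as the shared diagonal preference for
#' affinity propagation; higher q yields more, tighter clusters. The pipeline
#' default is q = 0.98.
#'
#' @param sim Similarity matrix (diagonal ignored).
#' @param q Quantile in [0, 1].
#' @return The preference value.
#' @export
preference_from_quantile <- function(sim, q = 0.98) {
  stopifnot(is.matrix(sim), nrow(sim) >= 2L)
  if (q < 0 || q > 1) stop("quantile q must lie in [0, 1]")
  off <- sim[row(sim) != col(sim)]
  unname(stats::quantile(off, probs = q, type = 7, na.rm = FALSE))
}

#' Affinity propagation clustering
#'
#' Standard message-passing over a similarity matrix: responsibilities
#' `r(i,k) <- s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]` and availabilities
#' `a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))` for
#' `i != k`, `a(k,k) <- sum_{i' != k} max(0, r(i',k))`, with messages damped
#' by `lambda` (new = (1 - lambda) * update + lambda * old). Exemplars are
#' the points with `r(k,k) + a(k,k) > 0`; every other point is assigned to
#' the exemplar of maximal similarity, ties broken by lowest index.
#'
#' @param sim Similarity matrix (finite off-diagonal values).
#' @param preference Shared diagonal preference (see
#'   [preference_from_quantile()]).
#' @param lambda Damping factor in `[0.5, 1)`; default 0.9 (high preferences
#'   oscillate under light damping).
#' @param max_iter Maximum number of message-passing iterations.
#' @param conv_iter Iterations the exemplar set must stay unchanged to
#'   declare convergence.
#' @return A `cluster_assignment` list: `exemplar_of` (named character),
#'   `exemplars`, `n_clusters`, `converged`, `iterations_run`.
#' @export
affinity_propagation <- function(sim, preference, lambda = 0.9,
                                 max_iter = 1000L, conv_iter = 100L) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (lambda < 0.5 || lambda >= 1) stop("damping lambda must lie in [0.5, 1)")
  g <- nrow(sim)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(g))
  if (g == 1L) {
    return(structure(list(exemplar_of = stats::setNames(ids, ids),
                          exemplars = ids, n_clusters = 1L, converged = TRUE,
                          iterations_run = 0L),
                     class = "cluster_assignment"))
  }
  s <- sim
  diag(s) <- preference
  if (any(!is.finite(s))) stop("similarities must be finite")
  msg <- .ap_messages(s, lambda, as.integer(max_iter), as.integer(conv_iter))
  evidence <- diag(msg$r) + diag(msg$a)
  iter <- msg$iterations
  converged <- msg$stable_for >= conv_iter
  tol <- 1e-9 * max(1, max(abs(s)))
  exemplars <- which(evidence > tol)
  # Degenerate ties: under exact symmetry the evidence of equivalent points
  # settles at 0 and the strict criterion selects none of them. Resolve
  # deterministically as if lower-index points carried an infinitesimally
  # higher preference: scan tied points in index order and promote one to
  # exemplar whenever no already-chosen exemplar suits it better than
  # representing itself.
  tied <- which(abs(evidence) <= tol)
  if (length(tied) > 0L) {
    for (k in tied) {
      served <- length(exemplars) > 0L && max(s[k, exemplars]) >= preference
      if (!served) exemplars <- sort(c(exemplars, k))
    }
    if (length(setdiff(exemplars, which(evidence > tol))) > 0L) {
      message("affinity propagation resolved degenerate zero-evidence ties by the lowest-index rule")
    }
  }
  if (length(exemplars) == 0L) {
    warning("affinity propagation found no exemplars; falling back to the point with maximal self-evidence")
    exemplars <- which.max(evidence)
    converged <- FALSE
  }
  if (!converged) {
    warning(sprintf("affinity propagation did not converge within %d iterations", max_iter))
  }
  # assignment: each point to the exemplar of maximal similarity, lowest
  # index winning ties; exemplars are their own exemplar
  sub <- s[, exemplars, drop = FALSE]
  pick <- apply(sub, 1L, function(row) which.max(row))  # which.max = first max
  assign_idx <- exemplars[pick]
  assign_idx[exemplars] <- exemplars
  structure(list(exemplar_of = stats::setNames(ids[assign_idx], ids),
                 exemplars = ids[exemplars],
                 n_clusters = length(exemplars),
                 converged = converged, iterations_run = iter),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d points, %d clusters, %s after %d iterations\n",
              length(x$exemplar_of), x$n_clusters,
              if (x$converged) "converged" else "NOT converged",
              x$iterations_run))
  invisible(x)
}

#' Convert a cluster assignment to a gene-set collection
#'
#' Clusters are named `CLUSTER1 ... CLUSTERn` in order of first appearance of
#' their exemplar; descriptions record the exemplar gene.
#'
#' @param assignment A [affinity_propagation()] result.
#' @return A [gene_set_collection()].
#' @export
clusters_to_collection <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ex <- assignment$exemplar_of
  members <- split(names(ex), factor(ex, levels = unique(unname(ex[assignment$exemplars]))))
  ord <- assignment$exemplars
  members <- members[ord]
  names(members) <- sprintf("CLUSTER%d", seq_along(members))
  gene_set_collection(members, stats::setNames(paste("exemplar", ord), names(members)))
}

#' Filter gene sets by size
#'
#' Retains sets with `min_size <= size <= max_size`. The pipeline default
#' (15 to 100 genes) excludes overly narrow or broad groups before
#' association testing.
#'
#' @param collection A [gene_set_collection()].
#' @param min_size,max_size Inclusive size bounds.
#' @return The filtered [gene_set_collection()].
#' @export
filter_gene_sets <- function(collection, min_size = 15L, max_size = 100L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_size > max_size) stop("min_size must not exceed max_size")
  sizes <- lengths(collection)
  keep <- sizes >= min_size & sizes <= max_size
  message(sprintf("size filter [%s, %s]: kept %d of %d gene sets",
                  format(min_size), format(max_size), sum(keep), length(collection)))
  out <- unclass(collection)[keep]
  if (length(out) == 0L) {
    return(structure(list(), description = character(0),
                     class = "gene_set_collection"))
  }
  gene_set_collection(out, attr(collection, "description")[keep])
}
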