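#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' `k_gj / (prod_v k_gv)^(1/S)`, the ratio of the gene's count to its
#' geometric mean across samples. Genes with a zero count in any sample are
#' excluded from the reference (the geometric mean would vanish). Factors are
#' rescaled to geometric mean 1 so they are comparable across cohorts.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @return Named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    stop("no gene has a strictly positive count in every sample; ",
         "filter samples or genes before size-factor estimation")
  }
  ref <- counts[usable, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  factors <- apply(ref, 2L, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  factors <- factors / exp(mean(log(factors)))  # geometric mean 1
  message(sprintf("size factors estimated from %d/%d genes positive in all %d samples",
                  sum(usable), nrow(counts), ncol(counts)))
  stats::setNames(factors, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix (genes x samples) with sample colnames.
#' @param factors Named size-factor vector covering every sample.
#' @return Numeric matrix of normalized expression values.
#' @export
normalize_counts <- function(counts, factors) {
  stopifnot(is.matrix(counts))
  if (is.null(colnames(counts)) || is.null(names(factors)) ||
      !setequal(colnames(counts), names(factors)) ||
      length(factors) != ncol(counts)) {
    stop("sample ids of counts and size factors do not match")
  }
  sweep(counts, 2L, factors[colnames(counts)], `/`)
}

#' Log2 transform with pseudocount
#'
#' @param expr Non-negative expression matrix.
#' @param pseudocount Added before taking log2 (default 1, so 0 maps to 0).
#' @return `log2(expr + pseudocount)`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  stopifnot(is.numeric(expr), pseudocount > 0)
  if (any(expr < 0)) stop("log_transform requires non-negative values")
  log2(expr + pseudocount)
}
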