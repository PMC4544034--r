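# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive full enumerations, not the shortcut formulas
# the package uses.

# Brute-force weighted-KS enrichment score: walk every rank position of the
# running sum and take the signed maximum deviation (positive wins exact ties
# in magnitude, matching the stated convention).
es_brute <- function(ranking, geneset, p = 1) {
  hit <- ranking$gene_id %in% geneset
  n <- nrow(ranking)
  n_hit <- sum(hit)
  w <- abs(ranking$score)^p
  sw <- sum(w[hit])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (sw > 0) w[i] / sw else 1 / n_hit
    } else {
      cur <- cur - 1 / (n - n_hit)
    }
    running[i] <- cur
  }
  hi <- max(running, 0)
  lo <- min(running, 0)
  if (hi + lo >= -1e-12) hi else lo  # positive wins magnitude ties
}

# Exhaustive exemplar-subset optimizer for affinity propagation's objective:
# net similarity = sum of preferences of exemplars + sum over non-exemplars
# of the best similarity to an exemplar. Returns the best subset, its value
# and the runner-up value (for margin checks).
ap_brute <- function(sim, preference) {
  g <- nrow(sim)
  s <- sim
  diag(s) <- preference
  best <- -Inf; best_set <- NULL; second <- -Inf
  for (mask in 1:(2^g - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(g) - 1L)) > 0)
    val <- length(ex) * preference
    if (length(ex) < g) {
      others <- setdiff(seq_len(g), ex)
      val <- val + sum(apply(s[others, ex, drop = FALSE], 1L, max))
    }
    if (val > best) {
      second <- best; best <- val; best_set <- ex
    } else if (val > second) {
      second <- val
    }
  }
  list(exemplars = best_set, value = best, runner_up = second)
}

# Random well-separated instance for the AP-vs-enumeration check: 2 or 3
# tight groups of 1-D points, similarity = negative squared distance. Returns
# NULL when the optimum is not separated from the runner-up by > 10%.
random_separated_instance <- function(g_max = 8L) {
  n_groups <- sample(2:3, 1L)
  g <- sample(n_groups:g_max, 1L)
  centers <- sample(seq(0, 40, by = 10), n_groups)
  pts <- centers[sample.int(n_groups, g, replace = TRUE)] + rnorm(g, sd = 0.3)
  if (length(unique(round(pts / 5))) < 2L) return(NULL)
  s <- -outer(pts, pts, function(a, b) (a - b)^2)
  rownames(s) <- colnames(s) <- sprintf("x%d", seq_len(g))
  preference <- median(s[row(s) != col(s)])
  oracle <- ap_brute(s, preference)
  margin <- abs(oracle$value - oracle$runner_up) / max(abs(oracle$value), 1e-12)
  if (!is.finite(margin) || margin <= 0.1) return(NULL)
  diag(s) <- NA_real_
  list(sim = s, preference = preference, oracle = oracle)
}

# Random ranked list + gene set for the ES oracle check
random_es_instance <- function() {
  n <- sample(10:60, 1L)
  scores <- round(rnorm(n, sd = 2), 4)
  ids <- sprintf("g%03d", sample.int(999, n))
  ord <- order(-scores, ids)
  ranking <- data.frame(gene_id = ids[ord], score = scores[ord],
                        stringsAsFactors = FALSE)
  n_hit <- sample(1:(n - 1L), 1L)
  list(ranking = ranking, geneset = sample(ids, n_hit),
       p = sample(c(0, 1, 1.5, 2), 1L))
}
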