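test_that("pearson similarity matches direct evaluation", {
  a <- c(1, 2, 3, 4)
  expr <- rbind(A = a, B = 2 * a + 3, C = -a, D = c(1, 2, 2, 4))
  colnames(expr) <- paste0("s", 1:4)
  s <- pearson_similarity(expr)
  expect_equal(s["A", "B"], 1)
  expect_equal(s["A", "C"], -1)
  # direct formula oracle for the irregular pair
  x <- a - mean(a); y <- expr["D", ] - mean(expr["D", ])
  expect_equal(s["A", "D"], unname(sum(x * y) / sqrt(sum(x^2) * sum(y^2))))
  expect_equal(s["A", "D"], 0.9233805, tolerance = 1e-7)
  expect_true(is.na(s["A", "A"]))
  expect_equal(s, t(s))
})

test_that("zero-variance genes are refused or dropped explicitly", {
  expr <- rbind(A = c(1, 2, 3, 4), FLAT = c(2, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:4)
  expect_error(pearson_similarity(expr), "FLAT")
  expect_message(s <- pearson_similarity(expr, drop_zero_variance = TRUE),
                 "dropping 1 zero-variance")
  expect_equal(rownames(s), "A")
})

test_that("preference quantile follows the linear-interpolation convention", {
  s <- matrix(0.3, 3, 3); diag(s) <- NA
  expect_equal(preference_from_quantile(s, 0.5), 0.3)
  expect_equal(preference_from_quantile(s, 0.98), 0.3)
  # off-diagonal multiset of balanced {1,2,3,4}: q = 0.5 interpolates to 2.5
  s2 <- matrix(NA_real_, 4, 4)
  s2[row(s2) != col(s2)] <- rep(1:4, 3)
  expect_equal(preference_from_quantile(s2, 0.5), 2.5)
  expect_equal(preference_from_quantile(s2, 1), 4)
  expect_error(preference_from_quantile(s2, 1.2), "\\[0, 1\\]")
})

test_that("affinity propagation handles the degenerate and tiny cases", {
  s1 <- matrix(NA_real_, 1, 1, dimnames = list("only", "only"))
  ap1 <- affinity_propagation(s1, preference = -1)
  expect_equal(ap1$n_clusters, 1L)
  expect_identical(unname(ap1$exemplar_of), "only")

  # two mutually dissimilar points: twin singletons beat one merged cluster
  s2 <- matrix(c(NA, -1, -1, NA), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ap2 <- affinity_propagation(s2, preference = -0.1)
  expect_equal(ap2$n_clusters, 2L)
  expect_identical(ap_brute(s2, -0.1)$exemplars, c(1L, 2L))

  # two tight groups of three: split exactly along the groups
  s6 <- matrix(-10, 6, 6); s6[1:3, 1:3] <- -0.1; s6[4:6, 4:6] <- -0.1
  diag(s6) <- NA
  rownames(s6) <- colnames(s6) <- paste0("p", 1:6)
  brute <- ap_brute(s6, -1)$exemplars
  expect_length(brute, 2L)
  expect_length(intersect(brute, 1:3), 1L)  # one exemplar per group
  expect_length(intersect(brute, 4:6), 1L)
  ap6 <- suppressMessages(suppressWarnings(affinity_propagation(s6, preference = -1)))
  expect_equal(ap6$n_clusters, 2L)
  expect_setequal(unname(ap6$exemplar_of[1:3]), ap6$exemplars[1L])
  expect_setequal(unname(ap6$exemplar_of[4:6]), ap6$exemplars[2L])
})

test_that("converged AP matches exhaustive exemplar optimization on separated instances", {
  withr::local_seed(2024L)
  done <- 0L
  while (done < 12L) {
    inst <- random_separated_instance()
    if (is.null(inst)) next
    ap <- suppressWarnings(affinity_propagation(inst$sim, inst$preference))
    if (!ap$converged) next
    got <- sort(match(ap$exemplars, rownames(inst$sim)))
    expect_identical(got, sort(inst$oracle$exemplars))
    done <- done + 1L
  }
})

test_that("exemplars are their own exemplars and assignments maximize similarity", {
  withr::local_seed(77L)
  pts <- c(rnorm(4, 0), rnorm(4, 10))
  s <- -outer(pts, pts, function(a, b) (a - b)^2)
  rownames(s) <- colnames(s) <- sprintf("x%d", 1:8)
  diag(s) <- NA
  ap <- suppressWarnings(affinity_propagation(s, preference_from_quantile(s, 0.5)))
  for (ex in ap$exemplars) expect_identical(unname(ap$exemplar_of[ex]), ex)
  expect_equal(ap$n_clusters, length(unique(ap$exemplar_of)))
})

test_that("cluster count is monotone non-decreasing in the preference", {
  cfg <- cohort_config(n_genes = 120L, cancer_types = "CT1",
                       n_tumor = 2L, n_normal = 40L,
                       modules = list(M1 = module_spec(20), M2 = module_spec(20),
                                      M3 = module_spec(20)),
                       dispersion = 0.05)
  tr <- build_truth(cfg, 55L)
  co <- simulate_counts(tr, 56L)
  lab <- co$CT1$labels
  lg <- log_transform(normalize_counts(co$CT1$counts,
         suppressMessages(estimate_size_factors(co$CT1$counts))))
  s <- pearson_similarity(lg[, lab$sample_ids[lab$class == 0L]])
  counts <- vapply(c(0.5, 0.8, 0.9, 0.98), function(q) {
    suppressWarnings(affinity_propagation(s, preference_from_quantile(s, q)))$n_clusters
  }, integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("planted modules are recovered from pooled normal expression", {
  skip_if_not_installed("mclust")
  cfg <- cohort_config(n_genes = 400L, cancer_types = c("CT1", "CT2"),
                       n_tumor = 5L, n_normal = 40L,
                       modules = list(M1 = module_spec(25), M2 = module_spec(18),
                                      M3 = module_spec(30), M4 = module_spec(15)),
                       dispersion = 0.05)
  tr <- build_truth(cfg, 71L)
  co <- simulate_counts(tr, 72L)
  lg <- do.call(cbind, lapply(co, function(x) {
    lab <- x$labels
    log_transform(normalize_counts(x$counts,
      suppressMessages(estimate_size_factors(x$counts))))[, lab$sample_ids[lab$class == 0L]]
  }))
  s <- pearson_similarity(lg)
  ap <- suppressWarnings(affinity_propagation(s, preference_from_quantile(s, 0.98)))
  modg <- names(which(tr$module_of != "background"))
  ari <- mclust::adjustedRandIndex(tr$module_of[modg], ap$exemplar_of[modg])
  expect_gte(ari, 0.8)
})

test_that("size filter keeps exactly the 15-100 band and validates bounds", {
  sizes <- c(14L, 15L, 33L, 100L, 101L)
  sets <- lapply(sizes, function(n) sprintf("s%d_g%03d", n, seq_len(n)))
  names(sets) <- sprintf("SET%d", sizes)
  coll <- gene_set_collection(sets)
  kept <- suppressMessages(filter_gene_sets(coll))
  expect_named(kept, c("SET15", "SET33", "SET100"))
  expect_length(suppressMessages(filter_gene_sets(kept, 1L, 10000L)), 3L)
  empty <- suppressMessages(filter_gene_sets(coll, 200L, 300L))
  expect_length(empty, 0L)
  expect_s3_class(empty, "gene_set_collection")
  expect_error(filter_gene_sets(coll, 50L, 20L), "min_size")
})

test_that("cluster assignments convert to a named partition collection", {
  s <- matrix(-10, 5, 5); s[1:2, 1:2] <- -0.1; s[3:5, 3:5] <- -0.1; diag(s) <- NA
  rownames(s) <- colnames(s) <- paste0("g", 1:5)
  ap <- suppressMessages(suppressWarnings(affinity_propagation(s, -1)))
  coll <- clusters_to_collection(ap)
  expect_equal(sort(unlist(coll, use.names = FALSE)), paste0("g", 1:5))
  expect_equal(sum(lengths(coll)), 5L)
  expect_match(names(coll), "^CLUSTER\\d+$")
})
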