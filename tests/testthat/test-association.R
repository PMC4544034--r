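two_class_expr <- function(vals0, vals1, genes = "g1") {
  n0 <- length(vals0) / length(genes); n1 <- length(vals1) / length(genes)
  e <- cbind(matrix(vals0, nrow = length(genes)),
             matrix(vals1, nrow = length(genes)))
  dimnames(e) <- list(genes, sprintf("s%d", seq_len(ncol(e))))
  lab <- phenotype_labels(colnames(e), rep(c(0L, 1L), c(n0, n1)))
  list(expr = e, labels = lab)
}

test_that("signal-to-noise matches hand evaluation incl. the variance floor", {
  d <- two_class_expr(c(0, 2), c(2, 4))
  expect_equal(signal2noise(d$expr, d$labels)$score, 2 / (2 * sqrt(2)),
               tolerance = 1e-10)
  # zero-variance classes engage the floors: sd <- 0.2*|mu|, or 0.2 at mu = 0
  d2 <- two_class_expr(c(0, 0, 0), c(1, 1, 1))
  expect_equal(signal2noise(d2$expr, d2$labels)$score, 2.5)
  # identical class distributions score zero
  d3 <- two_class_expr(c(5, 7, 9), c(5, 7, 9))
  expect_equal(signal2noise(d3$expr, d3$labels)$score, 0)
  d4 <- two_class_expr(c(1, 2), c(3))
  expect_error(signal2noise(d4$expr, d4$labels), "at least 2 samples")
})

test_that("signal-to-noise orders genes by score with lexicographic ties", {
  e <- rbind(zz = c(0, 0, 5, 5), aa = c(0, 0, 5, 5), mid = c(0, 0, 2, 2))
  colnames(e) <- paste0("s", 1:4)
  lab <- phenotype_labels(colnames(e), c(0, 0, 1, 1))
  r <- signal2noise(e, lab)
  expect_identical(r$gene_id, c("aa", "zz", "mid"))
  expect_true(all(diff(r$score) <= 0))
})

test_that("enrichment score on boundary and worked fixtures", {
  rk <- data.frame(gene_id = paste0("g", 1:6),
                   score = c(3, 2.5, 2, -1, -2, -3))
  expect_equal(enrichment_score(rk, paste0("g", 1:3)), 1)
  expect_equal(enrichment_score(rk, paste0("g", 4:6)), -1)
  rk5 <- data.frame(gene_id = paste0("g", 1:5),
                    score = c(2, 1, 0.5, -0.5, -1))
  expect_equal(enrichment_score(rk5, c("g1", "g3")), 0.8)
  expect_message(es <- enrichment_score(rk5, c("g1", "g3", "ABSENT")),
                 "1 gene-set members absent")
  expect_equal(es, 0.8)
  expect_error(enrichment_score(rk5, paste0("g", 1:5)), "covers every")
  expect_error(enrichment_score(rk5, "NOT_THERE"), "no members")
})

test_that("enrichment score equals the brute-force running sum on random instances", {
  withr::local_seed(90L)
  for (rep in 1:200) {
    inst <- random_es_instance()
    expect_equal(enrichment_score(inst$ranking, inst$geneset, inst$p),
                 es_brute(inst$ranking, inst$geneset, inst$p),
                 tolerance = 1e-12)
  }
})

test_that("negating scores and reversing the ranking negates the score", {
  withr::local_seed(91L)
  for (rep in 1:40) {
    inst <- random_es_instance()
    flipped <- inst$ranking[rev(seq_len(nrow(inst$ranking))), ]
    flipped$score <- -flipped$score
    expect_equal(enrichment_score(flipped, inst$geneset, inst$p),
                 -enrichment_score(inst$ranking, inst$geneset, inst$p),
                 tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, guarded and symmetric on null data", {
  cfg <- cohort_config(n_genes = 120L, cancer_types = "CT1",
                       n_tumor = 12L, n_normal = 12L,
                       modules = list(M1 = module_spec(15), M2 = module_spec(15)))
  tr <- build_truth(cfg, 61L)
  co <- simulate_counts(tr, 62L)
  norm <- normalize_counts(co$CT1$counts,
                           suppressMessages(estimate_size_factors(co$CT1$counts)))
  sets <- true_module_sets(tr)
  n1 <- permutation_null(norm, co$CT1$labels, sets, n_perm = 200L, seed = 5L)
  n2 <- permutation_null(norm, co$CT1$labels, sets, n_perm = 200L, seed = 5L)
  expect_identical(n1, n2)
  expect_false(identical(n1,
    permutation_null(norm, co$CT1$labels, sets, n_perm = 200L, seed = 6L)))
  expect_error(permutation_null(norm, co$CT1$labels, sets, n_perm = 0L),
               "at least 1")
  # exchangeable groups: null ES distribution centered at zero
  for (nm in rownames(n1)) {
    se <- sd(n1[nm, ]) / sqrt(ncol(n1))
    expect_lt(abs(mean(n1[nm, ])), 2.5 * se + 0.05)
  }
})

test_that("scoring converts null samples to p, NES and capped monotone FDR", {
  withr::local_seed(300L)
  nulls <- rbind(A = c(runif(50, 0, 0.5), -runif(49, 0, 0.5)),
                 B = c(runif(50, 0, 0.5), -runif(49, 0, 0.5)))
  obs <- c(A = 0.9, B = 0)  # A beats every same-sign null
  res <- score_sets(obs, nulls)
  expect_equal(res$p_nominal[res$set_name == "A"], 1 / 51)
  expect_gt(res$p_nominal[res$set_name == "B"], 0.9)
  expect_true(all(res$FDR >= 0 & res$FDR <= 1))

  # a set with no same-sign nulls is flagged, not silently scored
  nulls2 <- rbind(A = runif(99, 0.1, 0.5), B = runif(99, 0.1, 0.5))
  obs2 <- c(A = -0.4, B = 0.6)
  res2 <- score_sets(obs2, nulls2)
  expect_true(res2$flagged[res2$set_name == "A"])
  expect_equal(res2$p_nominal[res2$set_name == "A"], 1)
  expect_equal(res2$FDR[res2$set_name == "A"], 1)
  expect_true(is.na(res2$NES[res2$set_name == "A"]))

  # FDR never rises as |NES| grows, within each sign
  nulls3 <- matrix(rnorm(30 * 500, sd = 0.3), 30,
                   dimnames = list(sprintf("S%02d", 1:30), NULL))
  obs3 <- setNames(rnorm(30, sd = 0.45), rownames(nulls3))
  res3 <- score_sets(obs3, nulls3)
  for (sgn in c(1, -1)) {
    sub <- res3[!is.na(res3$NES) & sign(res3$NES) == sgn, ]
    sub <- sub[order(abs(sub$NES)), ]
    if (nrow(sub) > 1L) expect_true(all(diff(sub$FDR) <= 1e-12))
  }
})

test_that("signature calling implements the per-type significance count rule", {
  types7 <- c("BLCA", "BRCA", "COAD", "HNSC", "LIHC", "LUAD", "LUSC")
  tab <- rbind(
    data.frame(set_name = "CC", cancer_type = types7, FDR = 0.01),
    data.frame(set_name = "KICH_ONLY", cancer_type = types7,
               FDR = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)),
    data.frame(set_name = "KICH_ONLY", cancer_type = "KICH", FDR = 0.05),
    data.frame(set_name = "PAIR", cancer_type = types7,
               FDR = c(0.05, 0.05, 1, 1, 1, 1, 1)),
    data.frame(set_name = "NONE", cancer_type = types7, FDR = 0.5))
  out <- classify_signatures(tab)
  cat_of <- setNames(out$category, out$set_name)
  expect_identical(unname(cat_of["CC"]), "cross-cancer")
  expect_identical(unname(cat_of["KICH_ONLY"]), "cancer-specific")
  expect_identical(unname(cat_of["PAIR"]), "shared-2-3")
  expect_identical(unname(cat_of["NONE"]), "not-significant")
  # the boundary is strict: FDR exactly at the threshold is not significant
  tab2 <- data.frame(set_name = "EDGE", cancer_type = types7[1:4], FDR = 0.15)
  expect_identical(classify_signatures(tab2)$category, "not-significant")
})

test_that("top-fraction overlap counts shared extreme genes as percentages", {
  ids <- sprintf("g%03d", 1:100)
  base <- data.frame(gene_id = ids, score = seq(5, 0.05, length.out = 100))
  r2 <- base
  r2$gene_id <- c("g001", "g002", "g009", setdiff(ids, c("g001", "g002", "g009")))
  rankings <- list(A = base, B = r2)
  m <- top_fraction_overlap(rankings, fraction = 0.03)
  expect_equal(diag(m), c(A = 100, B = 100))
  expect_equal(m["A", "B"], 200 / 3, tolerance = 1e-10)
  expect_equal(m, t(m))
  expect_equal(top_fraction_overlap(list(X = base, Y = base))["X", "Y"], 100)
  r3 <- base; r3$gene_id <- rev(ids)
  expect_equal(top_fraction_overlap(list(X = base, Y = r3), 0.03)["X", "Y"], 0)
  expect_error(top_fraction_overlap(rankings, 0), "fraction")
  expect_error(top_fraction_overlap(list(A = base, B = base[1:50, ])),
               "same gene universe")
})

test_that("association is reproducible end to end for a fixed seed", {
  cfg <- cohort_config(n_genes = 150L, cancer_types = "CT1",
                       n_tumor = 10L, n_normal = 8L,
                       modules = list(UP = module_spec(15, active_types = "CT1",
                                                       delta = 2),
                                      NL = module_spec(15)))
  tr <- build_truth(cfg, 81L)
  co <- simulate_counts(tr, 82L)
  norm <- normalize_counts(co$CT1$counts,
                           suppressMessages(estimate_size_factors(co$CT1$counts)))
  sets <- true_module_sets(tr)
  r1 <- associate_gene_sets(norm, co$CT1$labels, sets, n_perm = 100L, seed = 9L)
  r2 <- associate_gene_sets(norm, co$CT1$labels, sets, n_perm = 100L, seed = 9L)
  expect_identical(r1, r2)
  expect_gt(r1$ES[r1$set_name == "UP"], 0.5)
  expect_lt(r1$p_nominal[r1$set_name == "UP"], 0.05)
})
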