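#' Specify one planted co-regulated gene module
#'
#' A module is a block of genes sharing a per-sample latent factor (rank-1
#' co-expression), optionally differentially expressed in tumors of a subset
#' of cancer types, and optionally expressed at an elevated baseline in a
#' single tissue (the surfactant-protein style tissue-restricted pattern).
#'
#' @param size Number of genes in the module (>= 2).
#' @param coexpr_beta Loading beta >= 0, in log2 units per latent s.d.
#' @param active_types Character vector of cancer types in which tumors shift.
#' @param delta Signed tumor log2 fold shift applied in each active type.
#' @param tissue_restricted_to Optional single cancer type whose samples
#'   (tumor and normal) get a baseline boost of `tissue_tau` log2 units.
#' @param tissue_tau Baseline log2 boost in the restricted tissue.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, coexpr_beta = 1, active_types = character(0),
                        delta = 0, tissue_restricted_to = NULL, tissue_tau = 0) {
  stopifnot(size >= 2L, coexpr_beta >= 0,
            is.null(tissue_restricted_to) || length(tissue_restricted_to) == 1L)
  structure(list(size = as.integer(size), coexpr_beta = coexpr_beta,
                 active_types = as.character(active_types), delta = delta,
                 tissue_restricted_to = tissue_restricted_to,
                 tissue_tau = tissue_tau),
            class = "module_spec")
}

#' Configure a synthetic multi-cancer tumor/normal cohort
#'
#' @param n_genes Total genes simulated.
#' @param cancer_types Character vector of cohort (cancer type) names.
#' @param n_tumor,n_normal Per-type sample counts (>= 2 each).
#' @param modules List of [module_spec()] objects; remaining genes are
#'   independent background.
#' @param dispersion Negative-binomial dispersion phi (> 0), scalar or one
#'   value per gene; variance = mean + phi * mean^2. The default 0.2
#'   (biological CV ~ 0.45) is typical of bulk human tissue cohorts;
#'   values near 0.05 correspond to near-isogenic material.
#' @param libsize_sigma Standard deviation (log scale) of the log-normal
#'   per-sample library-size factor.
#' @param baseline_logmu_range Range (log2 scale) from which per-gene baseline
#'   mean expression is drawn uniformly.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes, cancer_types, n_tumor, n_normal,
                          modules = list(), dispersion = 0.2,
                          libsize_sigma = 0.25,
                          baseline_logmu_range = c(3, 9)) {
  stopifnot(n_genes >= 1L, length(cancer_types) >= 1L,
            !anyDuplicated(cancer_types),
            all(n_tumor >= 2L), all(n_normal >= 2L),
            all(dispersion > 0), libsize_sigma >= 0,
            length(baseline_logmu_range) == 2L)
  sizes <- vapply(modules, function(m) m$size, integer(1))
  if (sum(sizes) > n_genes) {
    stop(sprintf("module sizes sum to %d but only %d genes configured",
                 sum(sizes), n_genes))
  }
  for (m in modules) {
    bad <- setdiff(c(m$active_types, m$tissue_restricted_to), cancer_types)
    if (length(bad)) stop("module references unknown cancer types: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 cancer_types = as.character(cancer_types),
                 n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                 modules = modules, dispersion = dispersion,
                 libsize_sigma = libsize_sigma,
                 baseline_logmu_range = baseline_logmu_range),
            class = "cohort_config")
}

#' Default synthetic cohort: six cancer types with planted signatures
#'
#' Desk-scale analog of a multi-type tumor/normal compendium: 2,000 genes,
#' six cancer types with 60 tumor / 30 normal samples each, and eleven
#' planted modules. Five are cross-cancer (tumor-shifted in >= 4 types,
#' arranged so every cancer type is covered by at least four of them — the
#' coverage pattern multi-type compendia show for cell-cycle programs),
#' three are specific to a single type, one is tissue-restricted (highly
#' expressed only in one tissue and down-regulated in that tissue's tumors,
#' the surfactant-protein pattern), and fifty-one are co-expressed but not
#' cancer-associated (nulls), on top of independent background genes. The
#' null modules matter: permutation-based set-level FDR is only stable when
#' non-associated sets dominate the tested collection, as they do in real
#' transcriptome-wide cluster catalogs.
#'
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function() {
  types <- c("BLCA", "BRCA", "COAD", "HNSC", "LIHC", "LUAD")
  mods <- list(
    CROSS_A = module_spec(33, active_types = types,       delta =  2),
    CROSS_B = module_spec(36, active_types = types,       delta =  2),
    CROSS_C = module_spec(17, active_types = types[1:5],  delta =  2),
    CROSS_D = module_spec(19, active_types = types[2:6],  delta =  2),
    CROSS_E = module_spec(24, active_types = types[c(1, 3, 5, 6)], delta = 2),
    SPEC_BLCA = module_spec(24, active_types = "BLCA",    delta =  2),
    SPEC_COAD = module_spec(17, active_types = "COAD",    delta = -2),
    SPEC_HNSC = module_spec(16, active_types = "HNSC",    delta =  2),
    # tissue-identity program: between-tissue contrast (tau) dominates the
    # within-tissue co-variation (beta), and tumors lose part, not all, of
    # the tissue-restricted expression
    TISSUE_LUAD = module_spec(39, coexpr_beta = 0.5, active_types = "LUAD",
                              delta = -1, tissue_restricted_to = "LUAD",
                              tissue_tau = 3)
  )
  null_sizes <- rep(c(15L, 16L, 17L, 18L, 19L, 20L), length.out = 51L)
  nulls <- lapply(null_sizes, module_spec)
  names(nulls) <- sprintf("NULL_%02d", seq_along(nulls))
  cohort_config(n_genes = 2000L, cancer_types = types,
                n_tumor = 60L, n_normal = 30L, modules = c(mods, nulls))
}

#' Null-data cohort for calibration: co-expressed modules, no tumor effect
#'
#' One cohort in which tumor and normal groups are exchangeable (all deltas
#' and tissue boosts zero) while modules remain co-expressed, so that
#' phenotype-permutation p-values should be uniform.
#'
#' @param n_sets Number of planted (null) modules.
#' @param set_size Genes per module.
#' @param n_per_group Samples per phenotype group.
#' @param n_genes Total genes (defaults to exactly covering the modules).
#' @return A [cohort_config()].
#' @export
null_cohort_config <- function(n_sets = 200L, set_size = 15L,
                               n_per_group = 30L,
                               n_genes = n_sets * set_size) {
  mods <- replicate(n_sets, module_spec(set_size), simplify = FALSE)
  names(mods) <- sprintf("NULLSET%03d", seq_len(n_sets))
  cohort_config(n_genes = n_genes, cancer_types = "COHORT1",
                n_tumor = n_per_group, n_normal = n_per_group, modules = mods)
}

#' Draw the fixed (non-count) layer of a synthetic cohort
#'
#' Assigns genes to modules, draws per-gene baselines and dispersions and
#' per-sample true library sizes. Deterministic given `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `synthetic_truth` list: `config`, `gene_ids`, `module_of`
#'   (named; "background" or module name), `baseline_log2`, `dispersion`,
#'   `samples` (data.frame: sample_id, cancer_type, class), `lib_size`.
#' @export
build_truth <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(seed)
  g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  mods <- config$modules
  if (is.null(names(mods)) && length(mods) > 0L) {
    names(mods) <- sprintf("MODULE%02d", seq_along(mods))
  }
  module_of <- rep("background", g)
  pool <- sample.int(g)  # random gene placement
  at <- 1L
  for (nm in names(mods)) {
    sz <- mods[[nm]]$size
    module_of[pool[at:(at + sz - 1L)]] <- nm
    at <- at + sz
  }
  names(module_of) <- gene_ids
  baseline <- stats::runif(g, config$baseline_logmu_range[1L],
                           config$baseline_logmu_range[2L])
  phi <- rep_len(config$dispersion, g)
  samples <- do.call(rbind, lapply(config$cancer_types, function(ct) {
    data.frame(
      sample_id = c(sprintf("%s_N%03d", ct, seq_len(config$n_normal)),
                    sprintf("%s_T%03d", ct, seq_len(config$n_tumor))),
      cancer_type = ct,
      class = rep(c(0L, 1L), c(config$n_normal, config$n_tumor)),
      stringsAsFactors = FALSE)
  }))
  lib <- stats::rlnorm(nrow(samples), meanlog = 0, sdlog = config$libsize_sigma)
  names(lib) <- samples$sample_id
  structure(list(config = c(config, list(module_names = names(mods))),
                 gene_ids = gene_ids, module_of = module_of,
                 baseline_log2 = stats::setNames(baseline, gene_ids),
                 dispersion = stats::setNames(phi, gene_ids),
                 samples = samples, lib_size = lib),
            class = "synthetic_truth")
}

#' Simulate negative-binomial counts from a synthetic truth
#'
#' The count of gene g in sample j is NB with mean `L_j * 2^m_gj` and
#' dispersion `phi_g` (variance = mean + phi * mean^2), where
#' `m_gj = baseline_g + tau * [tissue match] + beta * z_mj + delta * [tumor of
#' active type]` and `z_mj ~ N(0,1)` is shared by all genes of module m within
#' sample j (the co-regulation the clustering stage is meant to recover).
#'
#' @param truth A [build_truth()] result.
#' @param seed Integer seed (independent of the truth's seed).
#' @return List with one element per cancer type, each a list
#'   `counts` (integer matrix) and `labels` ([phenotype_labels()]).
#' @export
simulate_counts <- function(truth, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (any(truth$dispersion <= 0)) stop("dispersion must be positive")
  local_seed(seed)
  mods <- cfg$modules
  if (length(mods) > 0L && is.null(names(mods))) names(mods) <- cfg$module_names
  out <- list()
  for (ct in cfg$cancer_types) {
    sm <- truth$samples[truth$samples$cancer_type == ct, ]
    n_s <- nrow(sm)
    m <- matrix(truth$baseline_log2, nrow = cfg$n_genes, ncol = n_s)
    is_tumor <- sm$class == 1L
    for (nm in names(mods)) {
      spec <- mods[[nm]]
      idx <- which(truth$module_of == nm)
      z <- stats::rnorm(n_s)
      m[idx, ] <- m[idx, ] + spec$coexpr_beta * rep(z, each = length(idx))
      if (!is.null(spec$tissue_restricted_to) && spec$tissue_restricted_to == ct) {
        m[idx, ] <- m[idx, ] + spec$tissue_tau
      }
      if (ct %in% spec$active_types) {
        m[idx, is_tumor] <- m[idx, is_tumor] + spec$delta
      }
    }
    mu <- sweep(2^m, 2L, truth$lib_size[sm$sample_id], `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / truth$dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(truth$gene_ids, sm$sample_id))
    storage.mode(counts) <- "integer"
    out[[ct]] <- list(
      counts = counts,
      labels = phenotype_labels(sm$sample_id, sm$class))
  }
  out
}

#' True-module gene sets of a synthetic truth
#'
#' @param truth A [build_truth()] result.
#' @return A [gene_set_collection()] of the planted modules.
#' @export
true_module_sets <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  nms <- truth$config$module_names
  members <- lapply(nms, function(nm) names(which(truth$module_of == nm)))
  names(members) <- nms
  gene_set_collection(members,
                      stats::setNames(rep("planted module", length(nms)), nms))
}

#' Serialize a synthetic truth to JSON
#'
#' @param truth A [build_truth()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  x <- list(module_of = as.list(truth$module_of[truth$module_of != "background"]),
            baseline_log2 = as.list(round(truth$baseline_log2, 6)),
            lib_size = as.list(round(truth$lib_size, 6)),
            samples = truth$samples)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Seed the session RNG for the calling function only, restoring the previous
# state when the caller exits so its callers' RNG streams are unaffected.
local_seed <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(seed)
}
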