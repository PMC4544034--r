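# pancansig

Discovery and validation of co-regulated gene-set signatures from
multi-cohort tumor/normal RNA-seq data.

Cancers from different organs often share perturbed transcriptional
programs whose individual genes shift too little to stand out one at a
time. `pancansig` targets that setting: it clusters genes into de-novo
co-regulated sets from their expression over *normal* tissue, tests every
set for tumor/normal association separately in each cancer type, classifies
sets as **cross-cancer** (significant in ≥ 4 types) or **cancer-specific**
(significant in exactly one), and distills compact diagnostic gene panels
whose performance is measured by leave-one-out cross-validation. It is
aimed at computational biologists who want a transparent, fully
reproducible re-implementation of this analysis style — every stage is a
documented R function, and a built-in negative-binomial cohort simulator
with planted co-regulated modules makes the whole pipeline testable without
downloading any cohort.

## Methods at a glance

* **Normalization** — median-of-ratios size factors
  $s_j = \mathrm{median}_g\, k_{gj}/(\prod_v k_{gv})^{1/S}$ over genes
  positive in all samples, rescaled to geometric mean 1.
* **Clustering** — affinity propagation on Pearson correlations between
  gene profiles over all normal samples pooled across types; the diagonal
  preference is the 0.98 quantile of the similarities; clusters outside
  15–100 genes are discarded.
* **Association** — genes ranked by signal-to-noise
  $S2N = (\mu_T-\mu_N)/(\sigma_T+\sigma_N)$ (GSEA variance floors); each
  set scored by the weighted Kolmogorov–Smirnov running-sum enrichment
  statistic ($p = 1$); significance from 1,000 phenotype permutations with
  sign-separated NES and FDR; sets with FDR < 0.15 counted per type.
* **Panels** — top two genes per cross-cancer set by mean $|S2N|$ over the
  set's significant types; linear SVM ($C = 1$) LOOCV with fold-wise
  feature standardization (no leakage).

The methods vignette (`vignettes/coexpression-signatures.Rmd`) derives each
choice and documents what the simulator does and does not emulate.

## Worked example

The `analysis/` directory is the narrative workflow; each numbered script
reads the previous stage's files under `results/`:

```sh
Rscript analysis/01_simulate.R 17     # seed 17
Rscript analysis/02_normalize.R
Rscript analysis/03_cluster.R
Rscript analysis/04_association.R
Rscript analysis/05_signature_loocv.R
```

Stage 4 reports, per cancer type, how many of the 60 size-filtered
clusters are significant, then calls signatures:

```
  BLCA: 4/60 gene sets at FDR < 0.15
  ...
association: 4 cross-cancer, 6 cancer-specific, 1 shared-2-3 of 60 sets
```

Stage 5 extracts the panel from the cross-cancer clusters and evaluates it:

```
panel: 8 genes from 4 cross-cancer clusters
  BLCA: LOOCV accuracy 97.78% (88/90)
  BRCA: LOOCV accuracy 97.78% (88/90)
  COAD: LOOCV accuracy 94.44% (85/90)
  HNSC: LOOCV accuracy 96.67% (87/90)
  LIHC: LOOCV accuracy 95.56% (86/90)
  LUAD: LOOCV accuracy 93.33% (84/90)
tissue task (CLUSTER111 ~ TISSUE_LUAD, Jaccard 1.00): accuracy 98.33% (354/360 tumors)
```

Reading: an 8-gene panel drawn from four broadly perturbed co-expression
clusters separates tumors from normals in every cohort at 93–98% LOOCV
accuracy, and the recovered tissue-restricted cluster (which matches the
planted one exactly, Jaccard 1.0) identifies that tissue's tumors among all
360 tumors with 98.3% accuracy — the simulated analog of a lung-specific
surfactant-gene signature.

The same stages are available programmatically:

```r
library(pancansig)
res <- run_cohort_pipeline(default_cohort_config(), seed = 17)
res$signatures   # per-set category and significant types
res$loocv        # per-type panel accuracies
```

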