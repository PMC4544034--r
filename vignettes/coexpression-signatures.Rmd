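---
title: "Co-regulated gene-set signatures from multi-cohort tumor/normal expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-regulated gene-set signatures from multi-cohort tumor/normal expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-gene differential expression misses programs whose member genes each
shift only moderately but shift *together*. `pancansig` implements the
complementary view: genes are first grouped into de-novo co-regulated sets
from their expression over normal tissue, each set is then tested for
tumor/normal association separately in every cancer type, and sets are
classified by how many types they light up in — broadly perturbed programs
("cross-cancer signatures", significant at FDR < 0.15 in at least four
types) versus programs tied to one disease ("cancer-specific", significant
in exactly one). Finally, a compact panel (two top genes per cross-cancer
set) is evaluated as a tumor/normal classifier by leave-one-out
cross-validation (LOOCV).

All stages run on a synthetic multi-cancer compendium built by the package
itself, so the full pipeline is testable end to end with no external data.

## Pipeline and models

### Normalization

Raw counts are scaled by **median-of-ratios size factors**: for sample $j$,
$s_j = \mathrm{median}_g \, k_{gj} / (\prod_v k_{gv})^{1/S}$ over the genes
with a strictly positive count in every sample (the geometric-mean reference
is undefined otherwise); factors are rescaled to geometric mean 1 so they
are comparable across cohorts. Clustering uses $\log_2(\text{normalized}+1)$;
association uses the normalized *linear* values, the convention of
GSEA-style tools whose signal-to-noise statistic predates logged RNA-seq
input. Both choices are arguments, not constants.

### Co-expression clustering

Similarity between genes is the Pearson correlation of their profiles over
**all normal samples pooled across cancer types** — tumor status must not
shape the clusters that are later tested against tumor status. Clustering is
**affinity propagation**: messages
$r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}[a(i,k') + s(i,k')]$ and
$a(i,k) \leftarrow \min\{0,\, r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))\}$,
damped with $\lambda = 0.9$, at most 1,000 iterations, convergence declared
after 100 iterations of a stable exemplar set. The shared diagonal
preference is the $q = 0.98$ quantile of the off-diagonal similarities
(linear interpolation on the sorted values); raising it yields more, tighter
clusters. Numerical conventions that had to be pinned for reproducibility:

* argmax ties go to the lowest gene index, everywhere;
* under exact symmetry (identical points) the self-evidence
  $r(k,k)+a(k,k)$ of equivalent candidates settles at exactly zero and the
  strict "> 0" exemplar rule selects none of them; the package resolves
  such zero-evidence ties deterministically, as if lower-index points
  carried an infinitesimally larger preference, instead of jittering the
  similarities (jitter would break bit-reproducibility);
* non-convergence returns a flagged result with a warning, never silently.

Clusters of fewer than 15 or more than 100 genes are discarded before
association testing, excluding overly narrow or broad categories.

### Gene-set association

Within one cancer type, genes are ranked by **signal-to-noise**,
$S2N_g = (\mu_T - \mu_N)/(\sigma_T + \sigma_N)$, with the variance floor
$\sigma \leftarrow \max(\sigma, 0.2\,|\mu|)$ (and $\sigma \leftarrow 0.2$
at $\mu = 0$) that keeps low-variance genes from dominating. Each gene set
gets a **weighted Kolmogorov–Smirnov enrichment score**: walking down the
ranking, a running sum rises by $|S2N|^p / \sum_{\text{hits}} |S2N|^p$
($p = 1$) at member genes and falls by $1/(N - N_{hit})$ at non-members;
the ES is the signed maximum deviation (the positive extreme wins exact
magnitude ties). The null is **phenotype permutation** — labels are
shuffled over samples and the whole ranking-plus-ES computation repeats,
1,000 times by default. Gene permutation would be anti-conservative here
precisely because the sets are co-expressed. Normalization and FDR follow
the standard sign-separated procedure: $NES = ES / \mathrm{mean}|ES_{null}|$
over same-sign nulls, add-one nominal p-values (so $p \ge 1/(n_{perm}+1)$),
and FDR as the ratio of the pooled-null and observed NES tail fractions,
capped at 1 and forced monotone non-increasing in $|NES|$ within each sign.
A set with no same-sign null values is reported flagged with $p = FDR = 1$.

Two behaviors of this FDR are worth knowing. It is only stable when
*non-associated sets dominate the tested collection* (the observed-NES
denominator otherwise consists mostly of true positives, and chance
$p \approx 0.03$ events inherit small FDRs); and it penalizes a solitary
extreme set on its sign side, so a lone strongly down-regulated set can
carry nominal $p = 0.002$ yet FDR $\approx 0.4$. Both behaviors shaped the
synthetic defaults below.

### Signature calling and panels

Per set, the cancer types with FDR below the threshold (default 0.15) are
counted: $\ge 4$ types → cross-cancer, exactly 1 → cancer-specific, 2–3 →
shared-2-3, 0 → not-significant. From the cross-cancer sets a panel is
extracted: per set, the top `k = 2` genes by mean $|S2N|$ over the types in
which that set is significant (the source statistic and aggregation are
open choices in the field; the unweighted mean is the simplest defensible
one). The panel is evaluated by LOOCV with a linear soft-margin SVM
($C = 1$): for every fold, features are z-scored with the *training* fold's
mean and standard deviation only — fitting the scaler on all samples leaks
the held-out sample and is a regression-tested bug, not an option. Accuracy
is the proportion of held-out samples predicted correctly. The same
machinery runs the tissue task: tumors of one target type against all other
tumors, using a tissue-restricted cluster's genes as features.

## The synthetic compendium

`default_cohort_config()` emulates a multi-type tumor/normal compendium at
desk scale: 2,000 genes, six cancer types, 60 tumors + 30 normals each.
Counts are negative binomial with mean
$L_j \cdot 2^{\,b_g + \tau\cdot[\text{tissue}] + \beta z_{mj} + \delta\cdot[\text{tumor, active type}]}$
and variance $\mu + \phi\mu^2$; $z_{mj} \sim N(0,1)$ is one latent factor
per module and sample (rank-1 co-expression, the simplest structure that
produces coherent expression change), $L_j$ is log-normal sequencing depth
(sdlog 0.25), and baselines $b_g$ are uniform on $[3, 9]$ log2 counts.

The planted structure and the reasoning behind each choice:

* **Five cross-cancer modules** (δ = +2, i.e. 4-fold up in tumors), with
  activity patterns arranged so that *every* cancer type is covered by at
  least four of them — the coverage density real pan-cancer cell-cycle
  programs show. All five are up-regulated: proliferation programs rise in
  tumors, and a lone down-regulated set on its sign side is exactly the
  solitary-finding case the sign-separated FDR punishes.
* **Three single-type modules** (two up, one down at |δ| = 2) and one
  **tissue-restricted module**: baseline boost τ = 3 in one type's samples,
  loading β = 0.5 and tumor shift δ = −1 there. Tissue identity has to
  dominate the module's within-tissue co-variation (β < τ), otherwise no
  classifier can separate that tissue's tumors from others — with β = 1 and
  δ = −2 the net elevation equals the latent standard deviation and
  accuracy is capped near 0.81 regardless of method.
* **Fifty-one co-expressed null modules.** These are not filler: the
  permutation FDR is only usable when null sets dominate the collection,
  as they do in a real transcriptome-wide cluster catalog (thousands of
  clusters, a few dozen significant). With only ~10 tested sets the FDR
  mis-calls in both directions.
* **Dispersion φ = 0.2** (biological CV ≈ 0.45), the magnitude typical of
  bulk human tissue cohorts; φ ≈ 0.05 corresponds to near-isogenic
  material. This value matters beyond realism: with almost no idiosyncratic
  noise, a chance label split moves a rank-1 module coherently up the
  ranking, giving co-expressed sets a null ES tail near ±1 at ~2%
  probability *independent of sample size* (rank statistics are
  scale-free), which compresses every NES below ≈ 1.65 and makes FDR < 0.15
  undecidable. Realistic idiosyncratic noise is what separates true shifts
  from chance coherence.

What the generator deliberately does **not** model: batch effects, isoform
structure, gene-length bias, multi-factor module covariance, heavy-tailed
library sizes, and cohort-specific baselines beyond the one tissue module.
Passing tests on this cohort therefore demonstrate the *statistical
machinery* — calibration of the permutation null, recovery of coherent
planted structure, no leakage in validation — not robustness to the
technical artifacts of real compendia.

## Problem sizes and checks

The shipped checks run the null calibration at 200 sets × 1,000
permutations (nominal p < 0.05 fraction must sit in [0.03, 0.07]),
signature recovery and panel LOOCV on the full default cohort, clustering
recovery (adjusted Rand index ≥ 0.8 against planted modules, at β = 1 and
φ = 0.05, the tight-replication condition under which module correlation
is ≈ 0.9), size-factor recovery on library-size-only simulations
(near-Poisson dispersion, isolating scale recovery from estimator sampling
noise), and byte-identical outputs for repeated seeds. Exact-arithmetic
components are verified against independent brute-force oracles: the
enrichment score against a full running-sum enumeration (1,000 random
instances, 1e-12), affinity propagation against exhaustive exemplar-subset
optimization (instances with ≤ 8 points and a > 10% optimum margin).

## Known limitations

* Affinity propagation is dense $O(G^2)$ memory and time per iteration;
  the intended scale is ≤ 5,000 genes. Transcriptome-wide runs (20k+
  genes) need ~3.2 GB per message matrix and are not the target.
* At 90 samples per type, co-expressed sets retain a noticeable chance of
  nominal $p \approx 0.01$–0.05 in types where they are inactive; at
  FDR < 0.15 an occasional borderline mis-call of one set in one type is
  expected behavior of the statistic, not a defect.
* The per-type FDR is computed over whatever collection is supplied;
  feeding it a handful of sets (after aggressive filtering) degrades it,
  as described above.
* CLS files carry no sample identifiers; on read, positional identifiers
  are generated and class tokens are matched against the declared names.
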