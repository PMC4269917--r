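---
title: "Comparing sex-specific regulatory network ensembles"
author: "dimorphnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sex-specific regulatory network ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphnet)
```

## The problem

Many diseases — chronic obstructive pulmonary disease (COPD) among them —
present differently in men and women even when the average expression of
individual genes barely differs between the sexes. One mechanistic
explanation is that the same genes are wired to *different upstream
regulators* in each sex: genes can be differentially **co-expressed**, and
hence differentially co-regulated, without being differentially expressed.
`dimorphnet` implements a pipeline for detecting exactly this signal. It

1. builds a transcription-factor (TF) → gene *motif prior* by scanning
   promoter windows with position weight matrices (PWMs) against an
   empirical null;
2. refines that prior into a weighted regulatory network by **message
   passing** that integrates TF–TF interactions and gene co-expression;
3. turns single networks into **jack-knife ensembles** — one network per
   random subset of 10 subjects — so every edge has a score *distribution*
   per stratum (e.g. female vs male, sputum vs blood);
4. compares ensembles by per-edge *t*-statistics and by **differential
   targeting**: gene-set enrichment (GSEA) run on gene in-degrees rather
   than on expression;
5. screens for **disease-specific regulators** as TFs whose per-function
   targeting profiles anticorrelate between tissues (Spearman ρ < −0.4).

A synthetic-cohort generator reproduces the statistical structure this
analysis assumes, so every stage is testable end to end without any data
download.

## The message-passing model

The network core maintains three matrices: the TF × gene regulatory network
$W$, TF × TF cooperativity $P$, and gene × gene co-regulation $C$. All
three are first standardized so that each entry is
$(z_{\text{row}} + z_{\text{col}})/\sqrt 2$ (sample standard deviations;
degenerate rows or columns contribute 0). Evidence is exchanged through a
continuous Tanimoto kernel

$$T(X, Y)_{ij} = \frac{d_{ij}}{\sqrt{\lVert X_{i\cdot}\rVert^2 +
\lVert Y_{\cdot j}\rVert^2 - |d_{ij}|}}, \qquad d = XY,$$

with zero-denominator entries set to 0. Each iteration computes the
*responsibility* $R = T(P, W)$ (TF-side evidence) and *availability*
$A = T(W, C)$ (gene-side evidence) and relaxes the network toward their
average with learning rate $\alpha$:

$$W \leftarrow (1-\alpha)\,W + \alpha\,(R + A)/2 .$$

$P$ and $C$ are then re-estimated from the updated $W$ the same way. Their
Tanimoto self-similarity diagonals would otherwise dominate, so each
diagonal entry is replaced by the standard deviation of its row's
off-diagonal entries times the matrix dimension times
$e^{2\alpha\,\text{step}}$ (step counted from 0); matrices smaller than
3 × 3 have no off-diagonal dispersion to estimate and get a 0 diagonal.
Iteration stops when the mean absolute update of $W$ reaches `tol`.

Numerical choices, all exposed as arguments: $\alpha = 0.1$,
`tol = 1e-3`, `max_iter = 200`. In practice the loop converges in roughly
20–25 iterations on the problem sizes used here; hitting `max_iter` warns
and returns `converged = FALSE` rather than failing, because a
non-converged network is still informative for diagnosis. Final edge
scores live on a Z-score-like scale and may be negative; filtering on sign
is deliberately left to the edge caller.

## The motif prior

PWM scores are log-likelihood ratios
$\sum_i \log_2 P(b_i \mid \text{PWM}_i) / P(b_i \mid \text{background})$;
ambiguous bases contribute 0. The base of the logarithm is irrelevant to
site calls because the null is calibrated in the same base. A pseudocount
of $10^{-3}$ avoids $-\infty$ scores. Significance is empirical: each PWM's
threshold is the $(1 - 10^{-5})$ quantile of the scores of $10^6$ random
windows, drawn i.i.d. from background base frequencies or from supplied
background sequence. Both strands of the promoter window — positions
$[-750, +250)$ around the TSS in transcription orientation, minus-strand
genes reflected — are scanned, and any passing site makes a binary TF →
gene edge. TFs encoded on sex chromosomes are legitimate regulators of
autosomal genes and are retained in the prior even when sex-chromosome
*target* genes are excluded.

## Jack-knife ensembles and edge statistics

Each stratum's ensemble holds one network per replicate of exactly 10
subjects drawn without replacement *within* a replicate (subjects recur
across replicates), 100 replicates by default. Equal replicate size is the
point: it regularizes unequal group sizes (e.g. 42 female vs 84 male
subjects) so that every network is estimated from the same amount of data.
A covariate-matched sampling mode pairs each female replicate with a male
replicate matched exactly on GOLD stage and greedily nearest in
standardized age and pack-years, for checking that covariate imbalance is
not driving results.

Two ensembles are compared edge-wise with the unpaired pooled-variance
*t*-test (the same kernel used for differential expression, by design) and
Benjamini–Hochberg FDR across all TF × gene edges. An edge is
*sex-specific* when (1) the mean-score difference is at least 0.25, (2)
the FDR is below $10^{-5}$, and (3) the larger of the two ensemble means is
positive — likely real, and different both absolutely and statistically.
At study scale these cutoffs admit roughly one to five percent of all
possible edges; on the small synthetic systems in the test suite the
fraction is lower because fewer edges carry planted signal. The identical
distribution case is defined away from significance: identical constant
edge score vectors give $t = 0$, $p = 1$.

## Differential targeting

A gene's *in-degree* (sum of incoming edge weights) and a TF's
*out-degree* summarize how strongly an entity is targeted or targeting in
one network. Stacking degrees across an ensemble gives a gene-by-network
table formally identical to a gene-by-sample expression table, so GSEA
applies unchanged — ranking genes by the signal-to-noise metric
$(\mu_F - \mu_M)/(s_F + s_M)$ with each $s$ floored at $0.2\,|\mu|$ (0.2
when $\mu = 0$), walking the weighted Kolmogorov–Smirnov running sum
(weight exponent 1), and assessing significance by **gene-set permutation**:
random same-size sets scored on the fixed ranked list. NES divides ES by
the mean same-sign null magnitude; FDR follows the sign-stratified
NES-ratio procedure. When every distinct set of a given size can be
enumerated within `n_perm` draws the null is enumerated exhaustively, which
makes permutation p-values exact on tiny universes — the property the test
suite exploits. Set-size filters default to 15–500, standard for GSEA
tooling. Enrichment is reported as a signed score: $-\log_{10}(\text{FDR})$
for female-enriched sets (positive values), $+\log_{10}(\text{FDR})$ for
male-enriched (negative), with FDR floored at $1/(n_{\text{perm}}+1)$ so
scores stay finite. Ranking ties break by gene id, keeping runs
reproducible.

The same machinery runs per TF on its gene-by-network table of edge
weights, yielding a TF × gene-set signed-score profile per tissue. TFs
whose profiles over the selected sets (by default the 5 most
female-enriched plus the 5 most male-enriched from the gene-level screen;
ties break by set name) have Spearman ρ < −0.4 between tissues target these
functions in *opposite* sex directions in the two tissues — the candidate
disease-specific regulators. The *core subnetwork* restricts each tissue's
sex-specific edge list to edges from a discordant TF into a gene annotated
to a selected set.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` is a latent-activity model: in the designated
sex/tissue stratum each module TF gets an i.i.d. standard-normal activity
per sample, and each module gene receives `coupling` × (sum of its TFs'
activities) on top of an i.i.d. Gaussian baseline. This realizes precisely
the regime of interest — differential co-expression without differential
mean expression, since activities have mean zero. The generator also
plants: bimodal marker genes (24 by default, high in males, emulating
Y-chromosome probe sets) with optional mislabeled subjects for the PCA QC
flagger; mean shifts (`de_genes`) and variance inflation (`dv_genes`) for
the per-gene tests; covariates with the qualitative imbalance seen in COPD
cohorts (females younger with fewer pack-years; GOLD-stage distribution
shared between sexes). Default sizes follow the study design this pipeline
targets: 42 female and 84 male subjects, sputum and blood.

The generator deliberately omits microarray probe-level noise, batch
effects, correlated background co-expression, and RNA-seq count
distributions. Passing tests therefore demonstrate that the *methods*
recover planted structure under the model's assumptions, not that real
cohort data satisfy those assumptions. Effect-size magnitudes for real sex
differences are unknown; generator defaults are explicit choices, not
estimates of any real cohort.

## Problem sizes used by the test suite

Validation runs are scaled so that a complete check executes in minutes on
one core while preserving every statistical property being asserted:

- single-network recovery: 500 genes × 50 TFs, one module (3 TFs × 30
  genes, coupling 1.0), 40 samples — the planted-vs-decoy edge AUC is
  essentially saturated at this size;
- ensemble-level differential targeting: a 42-female / 84-male cohort over
  300 genes × 20 TFs, 20 networks per ensemble, 20 independent seeds;
- permutation controls and the cross-tissue discordance screen: 150–300
  genes, 12–20 networks per ensemble.

Ensemble sizes below the 100-network default trade per-edge power for
runtime; the planted effects are strong enough that recovery rates are
unaffected, which is itself checked across seeds. The 100-network,
400-subset jack-knife configuration is exercised explicitly at a small
gene count.

## Design decisions on open points

- **Pooled-variance t** (not Welch) everywhere a two-sample *t* is used:
  it is the conventional unpaired test, and using one kernel for
  expression, edges and degrees keeps the comparisons commensurable.
- **BH** is used wherever an FDR is required outside GSEA; GSEA retains
  its own permutation FDR.
- **Covariate-free models** throughout: the network stage cannot model
  covariates directly, so the expression-level tests are kept covariate-free
  for consistency, and covariate-matched resampling is offered as a control
  instead.
- Per-gene tests are run **per tissue**, matching the per-tissue network
  comparisons.
- Overlapping motif sites and both-strand duplicates are *not*
  deduplicated before the binary collapse — adjacency is 1 if any site
  passes, so downstream results are unaffected.
- Expression matrices must arrive complete; missing values are an error,
  never silently imputed.
- Constant rows in the clustering step get correlation 0 (distance 1) with
  a warning; zero-variance genes get co-expression 0 off-diagonal.
- The one-replicate degenerate case of a jack-knife plan (group size
  exactly 10) is allowed and yields identical replicates, which is the
  correct limiting behaviour.

## Known limitations

- Message-passing variants differ across implementations in normalization
  and diagonal details; this package fixes one variant. Differential
  conclusions at the ensemble level are expected, but not asserted, to be
  robust to the variant.
- Permutation significance from network ensembles should be read as a
  rank-ordering rather than a literal error rate; the gene-label and
  sex-label permutation controls exist precisely to calibrate expectations.
- A *single* sex-label permutation of unequal groups (42 vs 84) retains a
  residual female-fraction imbalance of a subject or two between the
  relabelled groups. When planted co-regulation is strong, degree-based
  GSEA can still detect that residual gradient — its gene-set-permutation
  null does not model the inter-gene correlation of a co-regulated module —
  so the permuted pipeline suppresses *edge calls* reliably but can retain
  nominal set-level enrichment. Averaging over several permutations, or
  comparing effect magnitudes rather than significance flags, is the
  appropriate reading of this control.
- The discordance screen needs at least 3 (by default 10) selected sets;
  with few informative sets ρ is noisy, and constant profiles are excluded
  as undefined.

## A worked example

```{r example, eval = FALSE}
mod <- module_spec("F", "sputum", sprintf("TF%03d", 1:2),
                   sprintf("G%04d", 1:20), coupling = 1.0)
truth <- generate_regulatory_truth(truth_config(
  n_tf = 10, n_genes = 100, prior_density = 0.08, modules = list(mod),
  decoys_per_module = 3, seed = 2))
cohort <- generate_cohort(cohort_config(
  n_female = 15, n_male = 20, n_genes = 100, modules = list(mod), seed = 3))

ens <- lapply(c(F = "F", M = "M"), function(sx) {
  plan <- jackknife_plan(cohort$metadata, sx, "sputum", reps = 20,
                         seed = child_seed(4, match(sx, c("F", "M"))))
  build_ensemble(cohort$expression$sputum, cohort$metadata, plan,
                 truth$motif_prior, truth$ppi)
})

ed <- edge_differential(ens$F, ens$M)
subnets <- select_sex_specific_edges(ed)
tab <- cbind(degree_table(ens$F, "gene_in"), degree_table(ens$M, "gene_in"))
res <- gsea(tab, rep(c("F", "M"), each = 20), truth$gene_sets,
            n_perm = 500, seed = 5, min_size = 5)
res[which.max(res$signed_score), ]
```

The planted module's gene set should attain the most positive signed score
with a small FDR — the README shows the numbers printed by exactly this
kind of run.
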