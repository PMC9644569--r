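---
title: "Hierarchical methylation deconvolution of the tumor microenvironment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical methylation deconvolution: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk tumor tissue profiled on Infinium methylation arrays is a mixture:
tumor cells, an angiogenic/non-immune compartment (epithelial, endothelial,
stromal cells) and an immune compartment spanning the myeloid and lymphoid
lineages. Because DNA methylation is highly cell-type specific and beta
values are linear in cell proportions (a beta value is a fraction of
methylated alleles, so a mixture's beta is the proportion-weighted average
of its components'), reference-based deconvolution can recover the cellular
composition of the microenvironment from a single bulk profile.

`tmedeconv` implements a tumor-type-specific *hierarchical* variant of this
idea. Rather than estimating all 17 terminal cell classes in one regression
— where closely related subtypes (naive vs memory T cells) are nearly
collinear — the composition is resolved layer by layer down a cell-lineage
tree, each layer using its own purpose-built CpG library:

* **L1** — tumor purity vs everything else (density-mode estimator, below);
* **L2** — immune vs angiogenic within the non-tumor mass;
* **L3A / L3B** — epithelial/endothelial/stromal; lymphoid/myeloid;
* **L4A / L4B** — granulocyte/mononuclear; NK/B/T;
* **L5A–L5D** — neutrophil/basophil/eosinophil; monocyte/DC;
  B naive/B memory; CD4 T/CD8 T;
* **L6A / L6B** — CD4 naive/memory/Treg; CD8 naive/memory.

Twelve libraries (L1 plus the eleven above) form one bundle per tumor type.
Each library separates its *focal children* and absorbs the same-branch
siblings as one *collapsed* class (e.g. L3A carries an `Immune` column so
immune signal in the profile has somewhere to go other than the three
angiogenic classes). Collapsed classes receive ranked markers exactly like
focal classes — they are genuine library classes, they are simply discarded
when mass is propagated.

## Layer 1: tumor purity

The purity library consists of *informative differentially methylated CpGs*
(iDMCs): probes shared by the tumor and normal training matrices whose beta
variance across tumor samples exceeds 0.005 (unbiased, n−1 denominator —
variance heterogeneity across tumors is what makes a probe informative
about purity), ranked by two-sided Wilcoxon rank-sum p-value and truncated
to the top 1000. Each iDMC is tagged hyper- or hypomethylated by comparing
mean tumor and normal beta.

For a new sample, hypomethylated iDMC betas are flipped to `1 − beta`, so
every transformed value rises with tumor content; a Gaussian-kernel density
of the transformed values is evaluated on the closed grid `[0, 1]` (step
0.001) and **purity is the grid argmax of the density**. The mode is used
rather than the mean because infiltrating cell signal and probe-specific
saturation perturb the tails, not the bulk of the distribution.

Numerical choices here, made once:

* *Rank-sum test*: exact enumeration when the smaller group has ≤ 10
  samples and the data are tie-free, otherwise the normal approximation
  with continuity and tie corrections (`stats::wilcox.test` semantics).
* *Ties in p*: broken by larger absolute tumor−normal mean beta
  difference, then lexicographic probe ID — the library is a pure function
  of its inputs.
* *Bandwidth*: Silverman's rule of thumb on the transformed values. The
  rule is not asserted to equal any upstream pipeline's choice; it is the
  standard default and is configurable (`bw =`). If the values are
  (near-)constant the bandwidth falls back to the grid step so a point
  mass still has a well-defined mode.
* *Mode ties* resolve to the lowest grid value; a `multimodal` flag is set
  when a second local maximum reaches 95% of the global maximum (bimodal
  purity distributions do occur, e.g. mixed tumor subpopulations, and the
  flag surfaces them instead of silently picking one).
* Transformed values are clipped to `[0, 1]` before density estimation
  (beta values can sit exactly on the bounds).
* Fewer than 10 usable iDMCs is an error; under half the library available
  attaches a low-coverage warning to the estimate.

## Marker selection: moderated one-vs-rest models

Layer libraries L2–L6B are built from a purified-cell reference panel. For
each library class, a one-vs-rest linear model is fitted per CpG on the
beta scale and the per-probe residual variances are shrunk toward a common
prior by empirical Bayes: the log residual variances are fitted by moments
to a scaled-F distribution (digamma/trigamma inversion, the latter solved
by monotone root-finding), yielding prior degrees of freedom `d0` and
prior variance `s0²`; the posterior variance is
`(d0·s0² + d_g·s_g²)/(d0 + d_g)` and the moderated t statistic uses it
with `d0 + d_g` degrees of freedom. The fit is delegated to limma
(`lmFit`/`eBayes`); the package's tests verify it against an independent
step-by-step transcription of these formulas, and a `d0_override` argument
exposes the two limits (0 → ordinary t, ∞ → full shrinkage) for
diagnostics. The design matrix accepts covariates, so adjusted models
(age, sex) are expressible for downstream epigenome-wide uses.

Per class the library keeps the **top 50 hypermethylated and top 50
hypomethylated** probes by moderated p-value (ties as in L1). "Top 100
hyper- and hypo-methylated CpGs" admits two readings — 100 total or 100
per direction; we take 50 + 50 = 100 per class, the convention of the
marker-selection framework this follows, and make the count configurable
(`n_markers`). If one direction runs short the other backfills with a
warning, so the count contract holds. The library stores the deduplicated
probe union and the per-class mean beta over those probes; means are the
standard reference statistic because beta mixing is linear.

The tumor reference class for L2 is built from the tumor *training*
samples whose L1 purity falls in the top tertile (minimum two). Training
tumors are themselves mixtures; using only the purest third limits
contamination of the tumor column by microenvironment signal. This is a
design choice the source material leaves open; it is recorded as such.

## Constrained projection and the cascade

Each layer solves the classic constrained projection problem

$$\min_w \; \lVert y - Xw \rVert^2 \quad \text{s.t.}\quad w \ge 0,\ \textstyle\sum_j w_j = 1,$$

with `X` the library's probe × class mean matrix restricted to the probes
present in the sample, on the beta scale (no logit/M-value transform — the
mixing model is linear in beta). The equality constraint is kept because
each layer's weights are *relative fractions of a separately fixed parent
mass*; a `sum_to_one = FALSE` variant (`Σw ≤ 1`) exists for comparison.

The solver enumerates candidate supports exactly: for every nonempty
subset of classes it solves the equality-constrained least-squares KKT
system with the remaining weights pinned at zero, keeps the feasible
candidates, and returns the one with the smallest objective. For a convex
QP the optimum's support must appear among these candidates, so the method
is exact; with at most 12 classes (real libraries have 3–5) the 2^k − 1
systems are trivial. Problems with more classes fall back to a primal
active-set iteration. Rank-deficient `X` (collinear class means) gets a
tiny ridge on the KKT system and a collinearity warning. Negative
round-off weights below 10⁻¹⁰ are clipped to zero and the vector
renormalized rather than truncated — conservation of mass takes priority.

The cascade then converts relative weights into absolute proportions:

1. layer 1: `Tumor = purity`, `Nontumor = 1 − purity`;
2. layer 2: the L2 projection's `Tumor` weight is **discarded** — tumor
   mass comes exclusively from L1 — and the `Immune`/`Angiogenic` weights
   are renormalized over the non-tumor mass;
3. layers 3–6: each library's focal-child weights are renormalized among
   themselves and multiplied by the *immediate parent's* absolute mass
   (each layer is weighted by the layer directly above, not re-anchored to
   L1); classes with no sub-library (NK below layer 4, the angiogenic
   classes below layer 3) are carried forward unchanged.

Children therefore sum to their parent *exactly* (to floating point), and
aggregating a deep layer up the tree reproduces the stored shallower
tables to 1e−12 — the package tests this as an invariant. If every focal
weight is zero the parent mass is split equally among the children with a
warning: conservation is preserved without inventing signal. Probe
coverage below half a library warns; below `max(10, k + 5)` probes errors.
Output columns follow the fixed canonical leaf order, so results are
stable across runs and machines.

## The synthetic cohort generator

The generators produce the data structure the method *assumes*, with known
ground truth, so every stage is testable without external downloads:

* a shared baseline beta vector (uniform on `[0.1, 0.9]`);
* a private marker block per terminal class **and a shared block per
  multi-leaf lineage node** (Immune, Lymphoid, Myeloid, Granulocyte, …),
  displaced ± `delta = 0.3` from baseline, half up and half down.
  The lineage blocks matter: real leukocyte lineages share methylation
  signatures, and without them the coarse layers (immune vs angiogenic,
  lymphoid vs myeloid) are only weakly identifiable because a collapsed
  class's mean dilutes each private block by the number of its leaves;
* a tumor/normal differential block of 5000 CpGs at the beta extremes
  (hyper: normal near 0.005, tumor near 0.995; hypo mirrored). Top-ranked
  iDMCs in practice are near-binary, and this is what makes the density
  mode track purity: a purity-`p` mixture has transformed iDMC betas
  concentrated near `p`;
* tumor training samples are purity-weighted tumor/normal blends (purity
  uniform on `[0.4, 0.95]`) with extra between-sample noise (sd 0.08) at
  the differential block only, so the 0.005 variance filter has signal on
  both sides;
* mixture proportions are drawn *hierarchically* — one symmetric
  Dirichlet draw (concentration 2 per child) at every internal tree node,
  multiplied down the tree — so the parent/child mass structure the
  cascade assumes is real in the data;
* measurement noise is additive Gaussian truncated to `[0, 1]`
  (sd 0.03 by default, the scale of Infinium technical replicates).
  Truncated-Gaussian rather than Beta noise keeps the convexity oracles
  exact (a noise-free mixture is *exactly* the convex combination of its
  archetypes); Beta noise would be marginally more realistic but breaks
  that property.

Default sample sizes — 6 replicates per reference class, 20 tumor and 20
normal training samples, 50 mixtures, 12 000 probes — are desk-scale
choices representative of purified-cell reference studies; all randomness
is a pure function of the seed (default 17, the leaf count), and the
tests and the acceptance script run at exactly these sizes.

What the generator does **not** emulate: Infinium type I/II probe
chemistry, batch effects, copy-number-driven beta shifts, immune-cell
reprogramming by the microenvironment, or tumor subclones. Passing tests
on this generator therefore demonstrate correctness of the algorithmic
pipeline under its own modeling assumptions, not field performance on
arbitrary clinical arrays.

## Scoring

`error_metrics()` works on the percent scale: signed error
`predicted(%) − true(%)`, absolute error, per-class RMSE across samples,
and per-class Pearson correlation. Correlation against a constant truth
vector is flagged `NA` (undefined), never reported as 0; correlation
p-values are descriptive only. The overall summary pools absolute error
over every class × sample cell, and equals the sample-count-weighted mean
of the per-class means (an identity the tests assert).

One property worth flagging: collapsing sibling subtypes (e.g. scoring
CD4 + CD8 as total T) does **not** necessarily reduce RMSE below the worst
subset. A collapsed class's signed error is the *sum* of its subsets'
errors, and in a hierarchical cascade sibling errors are positively
correlated through their shared parent-mass allocation, so the collapsed
RMSE is bounded by the sum of subset RMSEs (Minkowski) but can exceed the
worst one. Collapsing helps exactly when sibling biases anticorrelate —
as they do when the dominant error is the within-parent split.

## Known limitations

* Collapsed-class mean columns are fixed composition averages of their
  member classes; when a sample's composition within a collapsed branch
  differs strongly from the panel's, some off-target signal leaks into the
  focal classes. This is inherent to the collapsed-class design, is the
  dominant error source in the simulations, and shrinks as marker counts
  grow.
* The purity mode inherits a small bias from the iDMC beta range: with
  iDMCs spanning `[l, 1−l]` the mode estimates `l + (1−2l)·p`, so
  estimates compress slightly toward the middle at the extremes.
* Macrophages are deliberately absent from the hierarchy.
* The package starts from preprocessed beta matrices; IDAT parsing,
  normalization and detection-p filtering belong to upstream pipelines,
  and probe masks (cross-reactive, SNP, sex-chromosome probes) are
  accepted as user-supplied lists rather than recomputed.
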