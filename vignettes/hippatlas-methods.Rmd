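---
title: "Models and methods behind hippatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements for cross-species hippocampal spatial transcriptomics: what each
model assumes, which tunable parameters matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design choices
were settled.

## The data model

Expression is carried as sparse gene-by-cell count matrices (`dgCMatrix`,
genes as rows) read and written in the CellRanger-style MatrixMarket triple
(`matrix.mtx`, `features.tsv`, `barcodes.tsv`). Per-cell metadata travels in
a fixed-schema CSV cell table: species, modality (`reference` for
dissociated-nucleus data, `spatial` for sectioned data), section id, planar
coordinates in microns, a per-section longitudinal coordinate in mm, and —
once computed — subregion, cell type and a depth fraction (0 = superficial,
1 = deep). Spatial cells must carry section and coordinates; reference cells
must not. The longitudinal coordinate is constant within a section.

Normalization is the dominant single-cell convention: counts scaled to
10,000 per cell and transformed with the natural `log1p`. The scale factor
is recorded on the result; cells with zero total counts are kept as all-zero
columns and flagged rather than dropped. Highly variable genes are ranked by
plain variance of the log-normalized values with a lexicographic tie-break,
which makes HVG selection a deterministic function of the matrix.

## Clustering engine

All clustering stages share one engine: PCA via the eigen-decomposition of
the gene–gene covariance (deterministic, with each component's sign fixed so
its largest-magnitude loading is positive), an undirected unit-weight
k-nearest-neighbour graph in the embedding, and Leiden community detection
with the modularity objective. The contract is deliberately narrow: a
resolution parameter controls granularity and a seed makes every run
reproducible. Clusters below `min_size` (default 10) are merged into the
nearest cluster by centroid distance, because tiny modularity communities
are rarely meaningful at these sample sizes. Two consequences worth knowing:

* Granularity tracks resolution, not the "true" number of groups. A dense
  Gaussian blob legitimately splits at resolution 1; recovering two planted
  blobs as exactly two clusters needs a coarse resolution (0.1–0.3).
* At resolution 1.0 on the default reference simulation the engine resolves
  the taxonomy at the *type* level (ARI above 0.9 against planted types);
  subclass- and class-level structure is then read off by annotation, not by
  re-clustering.

Cluster-to-taxonomy annotation (`annotate_clusters()`) z-scores each cluster
centroid across genes and assigns the subclass whose marker program has the
highest mean z. Over-clustering is harmless here: several clusters may map
to one subclass, and the hierarchy-recovery summary counts distinct
subclasses per class.

## Subregion segmentation

Sections are segmented by spatial smoothing (each profile replaced by the
unweighted mean over itself and its `k_spatial = 10` nearest neighbours in
microns) followed by PCA and community detection. Two numerical choices
matter and were set after inspecting failure modes on simulated sections:

* The smoothed matrix is embedded **without** per-gene standardization.
  Subregion programs differ in overall magnitude; standardizing re-inflates
  per-gene noise and dilutes the band-level signal.
* Ten components and resolution 0.2 give band-level granularity. Higher
  resolutions resolve within-band cell-type mixtures instead of anatomy.

Clusters under 1% of the section are merged into the spatially adjacent
cluster with the highest centroid correlation. Cross-section matching uses
maximum-weight bipartite matching on centroid Pearson correlation (weights
shifted by +10 so that match cardinality dominates and the correlation only
orders equal-cardinality solutions); the reference section is the one with
the most cells, ties breaking toward the middle of the series so the
reference sits centrally on the axis. Consistency between matched clusters
is the Jaccard index of their top-50 marker sets (markers = largest
centroid-minus-section-mean difference); marker sets were chosen as the
Jaccard universe because they are independent of section geometry.

## Registration and replicability

Label transfer is intentionally simple: Pearson correlation of each spatial
cell's log profile against per-type reference centroids over the reference
HVG set, assign the argmax, break exact ties toward the type with more
reference cells. Cells with zero profile variance, or whose best correlation
falls below `c_min = 0.1`, stay "unassigned" with a reason flag — the
correlation flavour, gene set and unassignment floor are configuration, not
hidden defaults. Replicability is scored by neighbour voting: cells of both
datasets are placed on shared HVGs, each cell of one dataset is scored by
the fraction of its `k` Spearman-nearest neighbours in the other dataset
that carry a candidate type, and the score is summarised as an AUROC against
the true labels, symmetrised across the two directions.

## Consensus co-clustering homology

For two species on a shared gene namespace (standing in for a 1:1 ortholog
table), cells are concatenated, jointly embedded and clustered once per
(resolution, seed) pair over the default grid {0.6, 1.0, 1.4} x 5 seeds.
For types *i* (species A) and *j* (species B) with joint-cluster counts
`n_ic`, `n_jc`, a run contributes

    P(i, j) = sum_c n_ic * n_jc / (n_i * n_j),

the probability that a random cell of each type lands in the same joint
cluster; the homology matrix is the mean over runs. The formula is bounded
in [0, 1] and invariant to cluster relabeling, which makes the consensus
average meaningful. A type is species-specific when its best proportion
against every type of the other species stays below `tau_specific = 0.1`,
and primate-specific when that holds against the mouse in both
primate-vs-mouse comparisons while its primate-to-primate best match exceeds
`tau_match = 0.3`. Whether the proportion should be row-normalized is not
determinable from the construct itself; the pairwise co-membership
probability was adopted because it needs no normalization convention.

## Positional statistics

Relative density profiles divide a type's per-section count by the section
total and renormalize to sum one; sections with fewer than `m_min = 50`
cells are excluded and listed. Longitudinal heterogeneity is the natural log
of the sample standard deviation (ddof = 1) of those relative values, with
the SD floored at 1e-6 so perfectly uniform profiles remain finite.
Anterior/posterior preference uses the sign and significance of a Spearman
correlation against the axis coordinate (exact p for eight or nine sections
without ties, t-approximation otherwise) rather than a centre-of-mass
threshold, because the trend test is directly testable against exact
permutation p-values. Species stored with a reversed longitudinal
convention (mouse, ventral to dorsal) have their calls flipped into the
primate anterior/posterior frame.

Gene-family scores sum the family's raw counts over the masked cells of a
section, divide by those cells' total counts, and z-score the per-section
fractions (ddof = 1). The U-shape test regresses the profile on the
normalized axis position and its square; a U requires a positive quadratic
coefficient at p < 0.05 with the vertex inside (0.2, 0.8). Exact fits
(which arise in analytic toys) are special-cased: zero residual variance
with non-zero curvature counts as p = 0.

Neighborhood enrichment counts unordered cross-type cell pairs within
`radius_um = 50` of each other and standardizes against a within-section
label-permutation null (mean and population SD over `n_perm = 1000` draws;
the exhaustive null is enumerated when `n!` fits in the permutation budget).
Pairs where either type has fewer than `min_cells = 10` cells, or the null
SD is zero, are NA by construction. The ligand–receptor score is a
deliberately simple product of mean log-normalized expression in sender and
receiver, gated to zero unless both genes are expressed (count >= 1) in at
least 10% of their cells.

## The synthetic generator

The generator is first-class, tested code, and its defaults are the study
conditions for every recovery test. It plants:

* a 20-subclass taxonomy (10 glutamatergic, 5 GABAergic, 5 non-neuronal)
  over 36 types, with CA2 and CA3 mouse-only, a merged CA2/3 subclass in
  all species' references (absent from mouse sections, which carry separate
  CA2/CA3 bands), and three primate-only subicular types
  (`Glu pSUB-deep-1`, `Glu pSUB-int-1`, `Glu pSUB-int-2`);
* marker programs as multiplicative log-scale effects: 12 class genes at
  1.5, 30 subclass genes at 2.5, 10 type genes at 2.0, plus 16-gene
  distinct programs (2.2) for the primate-only types, per-species GABA
  marker genes, two 4-gene potassium-channel-like families and a 30-gene
  ion-channel panel split across the two CA1 types. The effects sit in the
  range of curated cell-type markers (several-fold to near on/off) — weaker
  programs are not resolvable at these cell numbers, and the recovery
  calibrations the package promises (type-level ARI >= 0.9, transfer
  accuracy >= 0.9, segmentation ARI >= 0.8, 80% U-shape power) pin the
  scale;
* counts drawn negative-binomial (dispersion 0.15) around log-normal
  library sizes (median 2,500), with the spatial modality thinned
  binomially at capture 0.35; dispersion 0 is the deterministic limit used
  by noiseless recovery tests;
* section geometry: eight sections per species at species-matched spacing
  (0.5 / 0.25 / 0.1 mm), 600 cells each on an 800 um strip of stacked
  laminar bands with 40 um soma-free margins (dense cell-body layers are
  separated by sparse neuropil in tissue); the pre/para-subicular zone is
  split into superficial/intermediate/deep strata through Beta-distributed
  depth placement;
* longitudinal modes per type: linear anterior/posterior gradients (slope
  1.2), uniform, or `(a - 0.5)^2 + c`; the mouse axis is stored ventral to
  dorsal with a reversal flag; one subicular type is planted with opposite
  gradients in the two primates;
* section-level multiplicative modulation of the gene families in CA1:
  U-shaped (amplitude 2.6) for the HCN-like panel, linear posterior for the
  KCNK-like panel;
* composition tables giving each species its GABA fraction among neurons
  (0.10 / 0.14 / 0.18 from mouse to macaque) and GABA subclass shares with
  a rising VIP component; spatial sections re-weight classes toward
  glutamatergic neurons (0.78/0.07/0.15) because the sampled bands are
  soma-dense pyramidal and granular layers. No per-subregion proportion
  table was available to copy, so these are plausible values fixed in the
  taxonomy object and editable there.

What the generator does **not** emulate: batch effects or cross-modality
platform shifts beyond binomial thinning, doublets and ambient RNA,
sub-cellular binning or segmentation errors, many-to-many orthology, and
tissue curvature (bands are straight). Passing recovery tests therefore
demonstrate that the statistics recover the structures they claim under a
clean generative model — not that any given tissue dataset is free of the
confounds above.

## Scale and determinism

Default problem sizes — 1,500 genes, 3,000 reference cells per species,
eight 600-cell sections per species — were chosen so that a full
three-species recovery run completes in minutes on one CPU while every
subclass retains tens of cells. Every stochastic step takes an explicit
seed; the pipeline derives stage seeds deterministically from one global
seed and the stage name, and records all parameters in a provenance file.
The spec-level pipeline interface is `pipeline_config()` (YAML-backed,
unknown keys rejected) plus `run_pipeline()`; the package's functions and
this vignette are the intended user surface.

## Known limitations

* Wilcoxon DE on log-normalized values is rank-based and robust but not a
  count model; no shrinkage of fold changes is applied.
* The co-clustering proportion inherits the granularity of the joint
  clustering: types that only differ by programs smaller than the clustering
  can resolve will co-cluster with their siblings and cannot be called
  species-specific.
* Depth fractions come from the generator's geometry; deriving them for
  real sections requires band geometry estimation that is out of scope.
* The neighborhood permutation null conditions on the section's composition
  only; gradients of density *within* a section are part of the signal, not
  the null.
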