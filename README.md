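# hippatlas

Cross-species analysis of hippocampal spatial transcriptomics in R.

The mammalian hippocampus is organised into subregions (dentate gyrus, the
CA fields, subiculum and the pre/para-subicular complex) whose cell types,
laminar positions and longitudinal distributions differ between rodents and
primates. Studies that profile the hippocampus of several species with
serial-section spatial transcriptomics plus single-nucleus RNA-seq face the
same analysis chain every time:

- **Subregion segmentation** — per section, spatially smoothed expression is
  clustered (`spatial_smooth()` → `embed_pca()` → `cluster_cells()` inside
  `segment_section()`), clusters are matched one-to-one across sections by
  maximum-weight bipartite matching on centroid correlation, and consistency
  is summarised as the Jaccard index of top-50 marker sets
  (`match_subregions_across_sections()`).
- **Registration** — every spatial cell is registered onto the reference cell
  type with the highest Pearson correlation of its log-normalized profile
  against type centroids over reference HVGs (`type_centroids()`,
  `transfer_labels()`), quality-checked with a neighbour-voting AUROC
  (`neighbor_voting_auroc()`).
- **Cross-species homology** — cells of two species are jointly clustered
  over a grid of resolutions and seeds; for types *i*, *j* the co-clustering
  proportion is `P(i,j) = sum_c n_ic * n_jc / (n_i * n_j)`, averaged over
  runs (`homology_matrix()`). Types whose best proportion against the other
  species stays below a threshold are called species-specific
  (`call_species_specific()`, `call_primate_specific()`).
- **Positional statistics** — per-section relative densities
  (`positional_profile()`), longitudinal heterogeneity `ln(sd)` of those
  densities (`heterogeneity()`), anterior/posterior/uniform preference by
  Spearman trend (`classify_preference()`, with a reversal flag for the
  mouse ventral–dorsal convention), subregion dominance at the strict 0.4
  proportion rule (`subregion_dominance()`), gene-family scores as z-scored
  per-section count fractions (`gene_family_score()`), quadratic U-shape
  detection (`ushape_test()`), and permutation neighborhood enrichment
  (`nhood_enrichment()`, `axis_trend()`, `ligand_receptor_score()`).
- **Marker statistics** — Wilcoxon rank-sum DE with BH correction
  (`find_markers()`), expression-bin-matched module scores
  (`module_score()`), co-expression fractions, marker Venn overlaps,
  pseudobulk similarity over the 100 most variable genes, and
  direction-aware cross-species DEG overlap counts.

Because the original tissue datasets are far beyond desk scale, the package
ships a fully seeded synthetic generator (`default_taxonomy()`,
`simulate_reference()`, `simulate_sections()`) that plants a known
three-species taxonomy — 10 glutamatergic, 5 GABAergic and 5 non-neuronal
subclasses; mouse-only CA2/CA3; three primate-only subicular types —
together with laminar band geometry, longitudinal density gradients and a
binomially thinned spatial modality. Every analysis stage is validated by
recovering this planted structure.

## Worked example

```r
library(hippatlas)

tax <- default_taxonomy()
ref <- simulate_reference(tax, "macaque", n_cells = 3000, seed = 11)
spt <- simulate_sections(tax, "macaque", seed = 12)

nm_ref <- normalize_log_cp10k(ref$expr)
nm_spt <- normalize_log_cp10k(spt$expr)

# register spatial cells onto reference types
cent <- type_centroids(nm_ref,
                       setNames(ref$truth$cells$type, ref$truth$cells$cell_id),
                       select_hvgs(nm_ref, 1500))
tr <- transfer_labels(nm_spt, cent)
mean(tr$cell_type == spt$truth$cells$type)
#> [1] 0.9991667

# longitudinal profile of a posterior-enriched subicular type
cells <- spt$cells
cells$cell_type <- tr$cell_type
prof <- positional_profile(cells, "Glu pSUB-int-2", "axis")
classify_preference(prof)
#> # A tibble: 1 × 4
#>   preference   rho p_value n_sections
#>   <chr>      <dbl>   <dbl>      <int>
#> 1 posterior  0.929 0.00223          8
heterogeneity(prof)
#> [1] -2.738421
```

The transfer accuracy says 99% of spatial cells were registered to their
true planted type at the default capture rate (0.35); the profile calls the
type posterior-enriched with Spearman rho 0.93, matching its planted
longitudinal mode.

`run_pipeline(pipeline_config())` chains every stage (simulation, reference
clustering and hierarchy annotation, segmentation, registration,
cross-species homology, axis statistics, neighborhood enrichment) into one
seeded run with a summary report and optional TSV/JSON outputs.

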