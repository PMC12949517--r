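#' Default multi-species hippocampal cell-type taxonomy
#'
#' Builds the reference taxonomy used by the synthetic-data generator and by
#' the annotation stages: a three-level hierarchy (class -> subclass -> type)
#' with marker-gene programs, per-species presence flags, home subregions,
#' longitudinal axis modes and laminar modes. The roster mirrors the
#' cross-species hippocampal organisation this package targets: 10
#' glutamatergic subclasses (CA1, CA2, CA3, CA2/3, CA3/4, DG, SUB,
#' pSUB-deep, pSUB-int, Glu-HIP), 5 GABAergic subclasses (PVALB, CCK, VIP,
#' SST, LAMP5) and 5 non-neuronal subclasses (Astrocyte, Olig, OPC, VLMC,
#' Microglia). The CA2 and CA3 subclasses are flagged mouse-only (primates
#' carry the merged CA2/3 subclass instead), and the three subicular types
#' `Glu pSUB-deep-1`, `Glu pSUB-int-1` and `Glu pSUB-int-2` are flagged
#' primate-only. All flags, marker effects and composition tables are plain
#' tibbles and can be edited before simulation.
#'
#' Marker effects are additive on the log scale of the gene mean
#' (an effect of 1.4 multiplies the baseline mean by `exp(1.4) ~ 4`), in the
#' range of well-curated cell-type markers. Two potassium-channel-like gene
#' families (`HCN_like`, `KCNK_like`) and a 30-gene ion-channel panel split
#' across the two CA1 types are planted for the axis-profile analyses.
#'
#' @param n_genes total size of the shared gene namespace (default 1500).
#'   The namespace is shared across species and stands in for a 1:1 ortholog
#'   table.
#' @return an object of class `hipp_taxonomy`; see Details for components.
#' @export
default_taxonomy <- function(n_genes = 1500) {
  species <- c("macaque", "marmoset", "mouse")
  reversed_axis <- c(macaque = FALSE, marmoset = FALSE, mouse = TRUE)

  classes <- tibble::tibble(
    class = c("glutamatergic", "GABAergic", "non_neuronal"),
    abbr  = c("GLU", "GABA", "NN"))

  subclasses <- tibble::tibble(
    subclass = c("CA1", "CA2", "CA3", "CA2/3", "CA3/4", "DG", "SUB",
                 "pSUB-deep", "pSUB-int", "Glu-HIP",
                 "PVALB", "CCK", "VIP", "SST", "LAMP5",
                 "Astrocyte", "Olig", "OPC", "VLMC", "Microglia"),
    class = c(rep("glutamatergic", 10), rep("GABAergic", 5), rep("non_neuronal", 5)))

  # type roster: name parts, subclass, presence, home subregion, axis mode,
  # per-species axis overrides, laminar mode
  tdef <- function(type, subclass, mac, mar, mou, home, axis, laminar, overrides = NULL) {
    tibble::tibble(type = type, subclass = subclass,
                   macaque = mac, marmoset = mar, mouse = mou,
                   home_subregion = home, axis_mode = axis,
                   laminar_mode = laminar,
                   axis_mode_overrides = list(overrides))
  }
  types <- dplyr::bind_rows(
    tdef("Glu CA1-1", "CA1", TRUE, TRUE, TRUE, "CA1-pyr", "anterior", "none"),
    tdef("Glu CA1-2", "CA1", TRUE, TRUE, TRUE, "CA1-pyr", "posterior", "none"),
    tdef("Glu CA2-1", "CA2", FALSE, FALSE, TRUE, "CA2-pyr", "uniform", "none"),
    tdef("Glu CA3-1", "CA3", FALSE, FALSE, TRUE, "CA3-pyr", "uniform", "none"),
    tdef("Glu CA3-2", "CA3", FALSE, FALSE, TRUE, "CA3-pyr", "uniform", "deep"),
    tdef("Glu CA2/3-1", "CA2/3", TRUE, TRUE, TRUE, "CA2/3-pyr", "uniform", "none"),
    tdef("Glu CA2/3-2", "CA2/3", TRUE, TRUE, TRUE, "CA2/3-pyr", "uniform", "none"),
    tdef("Glu CA3/4-1", "CA3/4", TRUE, TRUE, TRUE, "CA3/4-pyr", "uniform", "none"),
    tdef("Glu CA3/4-2", "CA3/4", TRUE, TRUE, TRUE, "CA3/4-pyr", "anterior", "none"),
    tdef("Glu DG-1", "DG", TRUE, TRUE, TRUE, "DG-gr", "uniform", "none"),
    tdef("Glu DG-2", "DG", TRUE, TRUE, TRUE, "DG-gr", "uniform", "none"),
    tdef("Glu SUB-1", "SUB", TRUE, TRUE, TRUE, "SUB", "anterior", "none"),
    tdef("Glu SUB-2", "SUB", TRUE, TRUE, TRUE, "SUB", "uniform", "none"),
    tdef("Glu pSUB-deep-1", "pSUB-deep", TRUE, TRUE, FALSE, "pSUB-deep", "anterior", "deep"),
    tdef("Glu pSUB-deep-2", "pSUB-deep", TRUE, TRUE, TRUE, "pSUB-deep", "uniform", "deep"),
    tdef("Glu pSUB-deep-3", "pSUB-deep", TRUE, TRUE, TRUE, "pSUB-deep", "uniform", "deep"),
    tdef("Glu pSUB-int-1", "pSUB-int", TRUE, TRUE, FALSE, "pSUB-int", "posterior", "intermediate"),
    tdef("Glu pSUB-int-2", "pSUB-int", TRUE, TRUE, FALSE, "pSUB-int", "posterior", "intermediate"),
    tdef("Glu pSUB-int-4", "pSUB-int", TRUE, TRUE, TRUE, "pSUB-int", "anterior", "intermediate",
         overrides = c(marmoset = "posterior")),
    tdef("Glu pSUB-int-6", "pSUB-int", TRUE, TRUE, TRUE, "pSUB-sup", "uniform", "superficial"),
    tdef("Glu HIP-1", "Glu-HIP", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA PVALB-1", "PVALB", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA PVALB-2", "PVALB", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA CCK-1", "CCK", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA VIP-1", "VIP", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA VIP-2", "VIP", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA SST-1", "SST", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA SST-2", "SST", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA LAMP5-1", "LAMP5", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("GABA LAMP5-2", "LAMP5", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("Astrocyte-1", "Astrocyte", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("Astrocyte-2", "Astrocyte", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("Olig-1", "Olig", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("OPC-1", "OPC", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("VLMC-1", "VLMC", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"),
    tdef("Microglia-1", "Microglia", TRUE, TRUE, TRUE, NA_character_, "uniform", "none"))
  types <- dplyr::left_join(types, subclasses, by = "subclass")

  san <- function(x) gsub("[^A-Za-z0-9]", "", x)

  # gene namespace: named marker blocks + families + channel panel + background
  class_genes <- lapply(classes$abbr, function(a) sprintf("CL.%s.%02d", a, 1:12))
  names(class_genes) <- classes$class
  sc_genes <- lapply(subclasses$subclass, function(s) sprintf("SC.%s.%02d", san(s), 1:30))
  names(sc_genes) <- subclasses$subclass
  ty_genes <- lapply(types$type, function(t) sprintf("TY.%s.%02d", san(t), 1:10))
  names(ty_genes) <- types$type
  gaba_sc <- subclasses$subclass[subclasses$class == "GABAergic"]
  species_markers <- tidyr::expand_grid(species = species, subclass = gaba_sc, i = 1:2)
  species_markers$gene <- sprintf("SP.%s.%s.%d", toupper(substr(species_markers$species, 1, 3)),
                                  san(species_markers$subclass), species_markers$i)
  species_markers$effect <- 1.2
  species_markers$i <- NULL

  # the primate-only subicular types carry strong distinct programs on top
  # of their subclass identity (cortical-layer-like signatures)
  primate_only <- c("Glu pSUB-deep-1", "Glu pSUB-int-1", "Glu pSUB-int-2")
  ps_genes <- lapply(primate_only, function(t) sprintf("PS.%s.%02d", san(t), 1:16))
  names(ps_genes) <- primate_only

  families <- list(HCN_like = sprintf("HCNL%d", 1:4),
                   KCNK_like = sprintf("KCNKL%d", 1:4))
  channel_panel <- sprintf("CHAN%02d", 1:30)
  channel_programs <- list("Glu CA1-1" = channel_panel[1:15],
                           "Glu CA1-2" = channel_panel[16:30])

  named <- c(unlist(class_genes), unlist(sc_genes), unlist(ty_genes),
             unlist(ps_genes), species_markers$gene, unlist(families), channel_panel)
  n_bg <- n_genes - length(named)
  if (n_bg < 0) abort_validation("n_genes (%d) smaller than the %d named marker genes", n_genes, length(named))
  genes <- c(unname(named), sprintf("BG%04d", seq_len(n_bg)))

  # marker programs as named log-effect vectors
  mk <- function(g, e) stats::setNames(rep(e, length(g)), g)
  classes$markers <- lapply(classes$class, function(cl) mk(class_genes[[cl]], 1.5))
  subclasses$markers <- lapply(subclasses$subclass, function(s) {
    m <- mk(sc_genes[[s]], 2.5)
    if (s == "CA1") m <- c(m, mk(unlist(families), 1.0))  # family genes live in CA1
    m
  })
  types$markers <- lapply(types$type, function(t) {
    m <- mk(ty_genes[[t]], 2.0)
    if (t %in% names(channel_programs)) m <- c(m, mk(channel_programs[[t]], 1.5))
    if (t %in% names(ps_genes)) m <- c(m, mk(ps_genes[[t]], 2.2))
    m
  })

  # per-gene baseline means, fixed at taxonomy construction so that reference
  # and spatial simulations of any species share one generative program
  baseline <- with_seed(860317L, stats::setNames(stats::rlnorm(length(genes), log(0.6), 1.0), genes))

  composition <- list(
    non_neuronal_frac = 0.25,
    gaba_frac_of_neurons = c(mouse = 0.10, marmoset = 0.14, macaque = 0.18),
    gaba_subclass_shares = tibble::tribble(
      ~species,   ~PVALB, ~CCK, ~VIP, ~SST, ~LAMP5,
      "mouse",      0.30, 0.14, 0.12, 0.30,  0.14,
      "marmoset",   0.24, 0.15, 0.21, 0.26,  0.14,
      "macaque",    0.20, 0.14, 0.30, 0.22,  0.14))

  structure(list(species = species, reversed_axis = reversed_axis,
                 classes = classes[, c("class", "markers")],
                 subclasses = subclasses, types = types, genes = genes,
                 baseline = baseline, families = families,
                 channel_panel = channel_panel, channel_programs = channel_programs,
                 species_markers = species_markers, composition = composition),
            class = "hipp_taxonomy")
}

#' @export
print.hipp_taxonomy <- function(x, ...) {
  n_by_class <- table(x$subclasses$class)
  cat("<hipp_taxonomy> ", length(x$genes), " genes; subclasses: ",
      paste(sprintf("%s=%d", names(n_by_class), n_by_class), collapse = ", "),
      "; ", nrow(x$types), " types; species: ", paste(x$species, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Types present in a given species
#'
#' @param tax a `hipp_taxonomy`.
#' @param species species label.
#' @return tibble of the taxonomy's type rows present in `species`.
#' @export
types_present <- function(tax, species) {
  if (!species %in% tax$species) abort_validation("unknown species '%s'", species)
  tax$types[tax$types[[species]], , drop = FALSE]
}

# effective axis mode of a type in a species (per-species overrides applied)
type_axis_mode <- function(tax, type, species) {
  row <- tax$types[tax$types$type == type, ]
  if (!nrow(row)) abort_validation("unknown type '%s'", type)
  ov <- row$axis_mode_overrides[[1]]
  if (!is.null(ov) && species %in% names(ov)) unname(ov[[species]]) else row$axis_mode
}

#' Default subregion marker panel derived from a taxonomy
#'
#' One gene panel per named subregion, taken from the marker program of the
#' subclass that inhabits it (the superficial pre/para-subicular stratum uses
#' its resident type's markers). Used by [annotate_subregions()].
#'
#' @param tax a `hipp_taxonomy`.
#' @return named list: subregion -> character vector of genes.
#' @export
default_marker_panel <- function(tax) {
  sc_mk <- function(s) names(tax$subclasses$markers[[match(s, tax$subclasses$subclass)]])
  ty_mk <- function(t) names(tax$types$markers[[match(t, tax$types$type)]])
  list("DG-gr" = sc_mk("DG"),
       "CA1-pyr" = sc_mk("CA1"),
       "CA2-pyr" = sc_mk("CA2"),
       "CA3-pyr" = sc_mk("CA3"),
       "CA2/3-pyr" = sc_mk("CA2/3"),
       "CA3/4-pyr" = sc_mk("CA3/4"),
       "SUB" = sc_mk("SUB"),
       "pSUB-deep" = sc_mk("pSUB-deep"),
       "pSUB-int" = sc_mk("pSUB-int"),
       "pSUB-sup" = ty_mk("Glu pSUB-int-6"))
}
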