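#' Noise parameters for the synthetic generators
#'
#' @param dispersion negative-binomial dispersion of counts (size = 1 /
#'   dispersion). `0` gives the deterministic limit in which every cell of a
#'   type has counts exactly proportional to the type's expression program.
#' @param library_meanlog,library_sdlog log-normal library-size parameters
#'   (reference modality; the spatial modality is additionally thinned).
#' @param species_effect_sd standard deviation of the per-gene log-normal
#'   species perturbation of the shared programs.
#' @return a named list of class `hipp_noise`.
#' @export
noise_params <- function(dispersion = 0.15, library_meanlog = log(2500),
                         library_sdlog = 0.35, species_effect_sd = 0.08) {
  if (dispersion < 0) abort_validation("dispersion must be >= 0")
  structure(list(dispersion = dispersion, library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 species_effect_sd = species_effect_sd), class = "hipp_noise")
}

# genes x present-types matrix of relative expression for one species.
# Species effects are deterministic in the species label so that reference
# and spatial simulations share one generative program.
gene_mean_matrix <- function(tax, species, noise) {
  tp <- types_present(tax, species)
  genes <- tax$genes
  log_mu <- matrix(log(tax$baseline[genes]), nrow = length(genes), ncol = nrow(tp),
                   dimnames = list(genes, tp$type))
  sp_eff <- with_seed(derive_seed(97L, species),
                      stats::rnorm(length(genes), 0, noise$species_effect_sd))
  log_mu <- log_mu + sp_eff
  sp_mk <- tax$species_markers[tax$species_markers$species == species, ]
  for (j in seq_len(nrow(tp))) {
    row <- tp[j, ]
    add <- function(v) if (length(v)) log_mu[names(v), j] <<- log_mu[names(v), j] + v
    add(tax$classes$markers[[match(row$class, tax$classes$class)]])
    add(tax$subclasses$markers[[match(row$subclass, tax$subclasses$subclass)]])
    add(row$markers[[1]])
    mk <- sp_mk[sp_mk$subclass == row$subclass, ]
    if (nrow(mk)) log_mu[mk$gene, j] <- log_mu[mk$gene, j] + mk$effect
  }
  mu <- exp(log_mu)
  sweep(mu, 2, colSums(mu), "/")
}

# per-type sampling probabilities for one species, from the taxonomy's
# composition tables
type_probs <- function(tax, species) {
  tp <- types_present(tax, species)
  comp <- tax$composition
  nn <- comp$non_neuronal_frac
  gaba <- (1 - nn) * comp$gaba_frac_of_neurons[[species]]
  glu <- (1 - nn) - gaba
  p <- numeric(nrow(tp))
  is_glu <- tp$class == "glutamatergic"
  is_gaba <- tp$class == "GABAergic"
  is_nn <- tp$class == "non_neuronal"
  p[is_glu] <- glu / sum(is_glu)
  shares <- comp$gaba_subclass_shares
  sh <- unlist(shares[shares$species == species, -1])
  for (s in names(sh)) {
    idx <- is_gaba & tp$subclass == s
    if (any(idx)) p[idx] <- gaba * sh[[s]] / sum(idx)
  }
  p[is_nn] <- nn / sum(is_nn)
  stats::setNames(p / sum(p), tp$type)
}

# draw a genes x n count block for one expression program (relative means p,
# per-cell library sizes libs); dispersion 0 is the deterministic limit
draw_counts <- function(p, libs, dispersion) {
  mu <- p %o% libs
  if (dispersion <= 0) return(round(mu))
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate a reference (snRNA-seq-like) dataset for one species
#'
#' Cell types are sampled from the taxonomy's composition tables restricted
#' to the types present in the species; per-gene means are
#' `baseline * exp(class + subclass + type + species effects)`; counts are
#' negative-binomial around library sizes drawn log-normal. Fully
#' reproducible from `seed`.
#'
#' @param tax a `hipp_taxonomy`.
#' @param species species label.
#' @param n_cells number of cells.
#' @param noise a [noise_params()] object.
#' @param seed integer seed.
#' @return list with `expr` (sparse counts), `cells` (cell table tibble with
#'   annotation columns left NA) and `truth` (ground-truth list; see
#'   [simulate_sections()]).
#' @export
simulate_reference <- function(tax, species, n_cells = 3000,
                               noise = noise_params(), seed = 1L) {
  if (n_cells <= 0) abort_validation("n_cells must be > 0")
  tp <- types_present(tax, species)
  p_mat <- gene_mean_matrix(tax, species, noise)
  probs <- type_probs(tax, species)
  with_seed(seed, {
    type_of <- sample(names(probs), n_cells, replace = TRUE, prob = probs)
    libs <- stats::rlnorm(n_cells, noise$library_meanlog, noise$library_sdlog)
    counts <- matrix(0, length(tax$genes), n_cells)
    for (t in colnames(p_mat)) {
      idx <- which(type_of == t)
      if (length(idx)) counts[, idx] <- draw_counts(p_mat[, t], libs[idx], noise$dispersion)
    }
    cell_id <- sprintf("%s_ref_%05d", species, seq_len(n_cells))
    dimnames(counts) <- list(tax$genes, cell_id)
    expr <- expression_matrix(counts)
    cells <- tibble::tibble(cell_id = cell_id, species = species,
                            modality = "reference", section_id = NA_character_,
                            x_um = NA_real_, y_um = NA_real_, axis_mm = NA_real_,
                            subregion = NA_character_, cell_type = NA_character_,
                            depth_frac = NA_real_)
    truth_cells <- tibble::tibble(cell_id = cell_id, species = species,
                                  type = type_of,
                                  subclass = tp$subclass[match(type_of, tp$type)],
                                  class = tp$class[match(type_of, tp$type)])
    list(expr = expr, cells = cells,
         truth = list(cells = truth_cells, presence = tax$types[, c("type", tax$species)]))
  })
}

#' Default serial-section layout for one species
#'
#' Eight coronal sections with species-matched longitudinal spacing (macaque
#' 0.5 mm, marmoset 0.25 mm, mouse 0.1 mm) and a laminar band layout in
#' microns: dentate granule layer, CA pyramidal bands (merged CA2/3 in
#' primates, separate CA2 and CA3 in mouse), CA1, subiculum and a
#' pre/para-subicular zone that is subdivided into deep, intermediate and
#' superficial strata by depth.
#'
#' @param species species label.
#' @param n_sections number of sections (default 8).
#' @param n_cells cells per section (default 600).
#' @return tibble with `section_id`, `axis_mm`, `n_cells` and a `bands`
#'   list-column of (subregion, ymin, ymax) tibbles.
#' @export
default_section_specs <- function(species, n_sections = 8, n_cells = 600) {
  spacing <- c(macaque = 0.5, marmoset = 0.25, mouse = 0.1)[[species]]
  if (species %in% c("macaque", "marmoset")) {
    bands <- tibble::tibble(
      subregion = c("DG-gr", "CA3/4-pyr", "CA2/3-pyr", "CA1-pyr", "SUB", "pSUB"),
      ymin = c(0, 300, 600, 900, 1200, 1500),
      ymax = c(300, 600, 900, 1200, 1500, 2100))
  } else {
    bands <- tibble::tibble(
      subregion = c("DG-gr", "CA3/4-pyr", "CA3-pyr", "CA2-pyr", "CA1-pyr", "SUB", "pSUB"),
      ymin = c(0, 300, 600, 750, 900, 1200, 1500),
      ymax = c(300, 600, 750, 900, 1200, 1500, 2100))
  }
  tibble::tibble(section_id = sprintf("%s_S%02d", species, seq_len(n_sections)),
                 axis_mm = (seq_len(n_sections) - 1) * spacing,
                 n_cells = n_cells, bands = rep(list(bands), n_sections))
}

# longitudinal weight of an axis mode at normalized position a in [0,1]
axis_factor <- function(mode, a, slope = 1.2) {
  switch(mode,
         anterior = 1 + slope * (0.5 - a),
         posterior = 1 + slope * (a - 0.5),
         uniform = rep(1, length(a)),
         ushape = 0.1 + (a - 0.5)^2,
         abort_validation("unknown axis_mode '%s'", mode))
}

# per-section multiplicative modulation of the planted gene families
family_modulation <- function(family, a) {
  switch(family,
         HCN_like = pmax(0.1, 1 + 2.6 * ((a - 0.5)^2 - 1 / 12)),
         KCNK_like = 1 + 0.8 * (a - 0.5),
         rep(1, length(a)))
}

#' Simulate serial spatial sections for one species
#'
#' Emulates a lower-capture spatial modality: per section, cell types are
#' drawn with per-type probabilities following the planted longitudinal mode
#' (anterior = linearly decreasing with the normalized axis coordinate,
#' posterior = increasing, uniform = flat, ushape = proportional to
#' `(a - 0.5)^2 + c`); cells are placed uniformly inside their home
#' subregion band (laminar modes shift the depth distribution toward the
#' stated stratum); expression is the species' reference program thinned
#' binomially at `capture_rate`; the planted potassium-channel-like gene
#' families receive a section-level multiplicative modulation (U-shaped for
#' `HCN_like`, posterior-increasing for `KCNK_like`) in CA1 cells. For
#' species with a reversed longitudinal convention (mouse ventral-to-dorsal
#' storage) the axis modes act on the flipped coordinate.
#'
#' @param tax a `hipp_taxonomy`.
#' @param species species label.
#' @param specs section layout tibble, see [default_section_specs()].
#' @param capture_rate per-transcript capture probability in (0, 1].
#' @param noise a [noise_params()] object.
#' @param x_width_um width of the simulated tissue strip in microns
#'   (default 800; with the default band layout this gives a cell density
#'   of a few hundred cells per square millimetre).
#' @param axis_slope slope of the linear anterior/posterior density
#'   gradients (default 1.2; 0 makes every type uniform).
#' @param class_mix spatial-modality class proportions; the default
#'   oversamples glutamatergic neurons relative to the dissociated-nuclei
#'   composition, as the sampled bands are dominated by pyramidal and
#'   granule cell somata.
#' @param seed integer seed.
#' @return list with `expr`, `cells` (spatial cell table; annotation columns
#'   NA) and `truth` containing per-cell `cells` (type, subclass, class,
#'   subregion, depth), `axis_modes` (effective per-species mode per type),
#'   `families` (per-section planted multipliers) and `presence`.
#' @export
simulate_sections <- function(tax, species, specs = default_section_specs(species),
                              capture_rate = 0.35, noise = noise_params(),
                              x_width_um = 800,
                              class_mix = c(glutamatergic = 0.78, GABAergic = 0.07,
                                            non_neuronal = 0.15),
                              axis_slope = 1.2, seed = 1L) {
  if (!nrow(specs)) abort_validation("empty section specs")
  if (is.unsorted(specs$axis_mm)) abort_validation("specs must be sorted by axis_mm")
  if (capture_rate <= 0 || capture_rate > 1) abort_validation("capture_rate must be in (0, 1]")
  tp <- types_present(tax, species)
  p_mat <- gene_mean_matrix(tax, species, noise)
  base_probs <- type_probs(tax, species)
  # spatial sections oversample the dense pyramidal/granular layers relative
  # to the dissociated-nuclei mix, so the class proportions are re-weighted
  for (cls in names(class_mix)) {
    in_cls <- tp$class == cls
    base_probs[in_cls] <- base_probs[in_cls] / sum(base_probs[in_cls]) * class_mix[[cls]]
  }
  base_probs <- base_probs / sum(base_probs)
  rng <- range(specs$axis_mm)
  a_norm <- if (diff(rng) > 0) (specs$axis_mm - rng[1]) / diff(rng) else rep(0.5, nrow(specs))
  a_eff <- if (isTRUE(tax$reversed_axis[[species]])) 1 - a_norm else a_norm
  modes <- vapply(tp$type, function(t) type_axis_mode(tax, t, species), character(1))
  ca1_types <- tp$type[tp$subclass == "CA1"]

  depth_draw <- function(mode, n) {
    switch(mode,
           superficial = stats::rbeta(n, 2, 12),
           intermediate = stats::rbeta(n, 20, 20),
           deep = stats::rbeta(n, 12, 2),
           stats::runif(n))
  }

  with_seed(seed, {
    sec_list <- vector("list", nrow(specs))
    cnt_list <- vector("list", nrow(specs))
    for (s in seq_len(nrow(specs))) {
      n <- specs$n_cells[s]
      bands <- specs$bands[[s]]
      w <- base_probs * vapply(modes, function(m) axis_factor(m, a_eff[s], axis_slope), numeric(1))
      # types whose home band is absent from this species' layout (e.g. the
      # merged CA2/3 band in mouse sections) are not sampled spatially
      home_band <- ifelse(tp$home_subregion %in% c("pSUB-deep", "pSUB-int", "pSUB-sup"),
                          "pSUB", tp$home_subregion)
      w[!is.na(home_band) & !home_band %in% bands$subregion] <- 0
      w <- w / sum(w)
      type_of <- sample(names(w), n, replace = TRUE, prob = w)
      rows <- match(type_of, tp$type)
      home <- tp$home_subregion[rows]
      band_of <- ifelse(home %in% c("pSUB-deep", "pSUB-int", "pSUB-sup"), "pSUB", home)
      scatter <- is.na(band_of)
      if (any(scatter)) {
        heights <- bands$ymax - bands$ymin
        band_of[scatter] <- sample(bands$subregion, sum(scatter), replace = TRUE,
                                   prob = heights / sum(heights))
      }
      depth <- numeric(n)
      for (lm in unique(tp$laminar_mode[rows])) {
        idx <- which(tp$laminar_mode[rows] == lm)
        depth[idx] <- depth_draw(lm, length(idx))
      }
      # 40 um soma-free margins at band boundaries (sparse neuropil zones
      # separate the dense cell-body layers in tissue)
      bi <- match(band_of, bands$subregion)
      margin <- 40
      y <- (bands$ymin[bi] + margin) +
        depth * (bands$ymax[bi] - bands$ymin[bi] - 2 * margin)
      x <- stats::runif(n, 0, x_width_um)
      # true subregion: the home stratum for typed cells; the geometric
      # stratum (depth thirds of the pre/para-subicular zone) for scattered
      # cells
      subregion <- ifelse(is.na(home), band_of, home)
      geo_psub <- is.na(home) & band_of == "pSUB"
      subregion[geo_psub] <- c("pSUB-sup", "pSUB-int", "pSUB-deep")[
        findInterval(depth[geo_psub], c(1 / 3, 2 / 3)) + 1]

      libs <- stats::rlnorm(n, noise$library_meanlog, noise$library_sdlog)
      counts <- matrix(0, length(tax$genes), n)
      for (t in unique(type_of)) {
        idx <- which(type_of == t)
        p <- p_mat[, t]
        if (t %in% ca1_types) {
          for (fam in names(tax$families)) {
            g <- tax$families[[fam]]
            p[g] <- p[g] * family_modulation(fam, a_norm[s])
          }
          p <- p / sum(p)
        }
        base <- draw_counts(p, libs[idx], noise$dispersion)
        if (capture_rate < 1) {
          base[] <- stats::rbinom(length(base), size = as.integer(round(base)), prob = capture_rate)
        }
        counts[, idx] <- base
      }
      cell_id <- sprintf("%s_%05d", specs$section_id[s], seq_len(n))
      dimnames(counts) <- list(tax$genes, cell_id)
      cnt_list[[s]] <- counts
      sec_list[[s]] <- tibble::tibble(
        cell_id = cell_id, species = species, modality = "spatial",
        section_id = specs$section_id[s], x_um = x, y_um = y,
        axis_mm = specs$axis_mm[s], subregion = subregion,
        cell_type = type_of, depth_frac = depth)
    }
    full <- dplyr::bind_rows(sec_list)
    expr <- expression_matrix(do.call(cbind, cnt_list))
    truth_cells <- dplyr::select(full, "cell_id", "species", "section_id",
                                 "axis_mm", "subregion", "depth_frac",
                                 type = "cell_type")
    truth_cells$subclass <- tp$subclass[match(truth_cells$type, tp$type)]
    truth_cells$class <- tp$class[match(truth_cells$type, tp$type)]
    cells <- dplyr::mutate(full, subregion = NA_character_, cell_type = NA_character_)
    fam_tbl <- dplyr::bind_rows(lapply(names(tax$families), function(fam) {
      tibble::tibble(family = fam, section_id = specs$section_id,
                     axis_mm = specs$axis_mm,
                     multiplier = family_modulation(fam, a_norm))
    }))
    list(expr = expr, cells = cells,
         truth = list(cells = truth_cells,
                      axis_modes = tibble::tibble(type = tp$type, axis_mode = unname(modes)),
                      families = fam_tbl,
                      presence = tax$types[, c("type", tax$species)],
                      reversed_axis = unname(tax$reversed_axis[[species]])))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the MatrixMarket triple, the cell table CSV and a
#' `ground_truth.json` with the per-cell truth and planted structure.
#'
#' @param sim result of [simulate_reference()] or [simulate_sections()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_triple(sim$expr, dir)
  write_cell_table(sim$cells, file.path(dir, "cells.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
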