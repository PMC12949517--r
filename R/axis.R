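#' Positional profile of a cell type along a hippocampal axis
#'
#' For `coordinate = "axis"`: per section, the relative density
#' `n_entity / n_all`, renormalized to sum to one over included sections;
#' sections with fewer than `m_min` cells are excluded and listed in the
#' `excluded_sections` attribute. For `"depth"` / `"proximodistal"`, decile
#' bins of `depth_frac` / `x_um` replace sections.
#'
#' @param cells spatial cell table with `cell_type` filled (ground truth or
#'   transferred labels).
#' @param entity cell-type label.
#' @param coordinate one of "axis", "depth", "proximodistal".
#' @param m_min minimum cells per section for inclusion (default 50).
#' @return tibble of class `hipp_axis_profile` (position, n_entity, n_all,
#'   relative) with attributes `entity`, `coordinate`, `excluded_sections`,
#'   `absent` (TRUE when the entity never occurs).
#' @export
positional_profile <- function(cells, entity, coordinate = c("axis", "depth", "proximodistal"),
                               m_min = 50) {
  coordinate <- match.arg(coordinate)
  sp <- cells[cells$modality == "spatial", ]
  if (coordinate == "axis") {
    tab <- sp |>
      dplyr::group_by(.data$section_id, .data$axis_mm) |>
      dplyr::summarise(n_all = dplyr::n(),
                       n_entity = sum(.data$cell_type == entity, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::arrange(.data$axis_mm)
    if (nrow(tab) < 3) abort_validation("need >= 3 sections")
    excluded <- tab$section_id[tab$n_all < m_min]
    tab <- tab[tab$n_all >= m_min, ]
  } else {
    coord <- if (coordinate == "depth") sp$depth_frac else sp$x_um
    keep <- !is.na(coord)
    if (sum(sp$cell_type[keep] == entity, na.rm = TRUE) < 20 &&
        any(sp$cell_type == entity, na.rm = TRUE)) {
      abort_validation("need >= 20 cells of '%s' for binned profiles", entity)
    }
    br <- stats::quantile(coord[keep], probs = seq(0, 1, 0.1), names = FALSE)
    br <- unique(br)
    bin <- cut(coord[keep], breaks = br, include.lowest = TRUE, labels = FALSE)
    mid <- (br[-length(br)] + br[-1]) / 2
    tab <- tibble::tibble(bin = bin, ct = sp$cell_type[keep]) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n_all = dplyr::n(),
                       n_entity = sum(.data$ct == entity, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(section_id = sprintf("bin%02d", .data$bin),
                    axis_mm = mid[.data$bin]) |>
      dplyr::select("section_id", "axis_mm", "n_all", "n_entity")
    excluded <- character()
  }
  rel <- tab$n_entity / tab$n_all
  absent <- sum(tab$n_entity) == 0
  tab$relative <- if (absent) rep(0, nrow(tab)) else rel / sum(rel)
  out <- tibble::new_tibble(tab, class = "hipp_axis_profile")
  attr(out, "entity") <- entity
  attr(out, "coordinate") <- coordinate
  attr(out, "excluded_sections") <- excluded
  attr(out, "absent") <- absent
  out
}

#' Longitudinal heterogeneity of a positional profile
#'
#' The natural log of the sample standard deviation (ddof = 1) of the
#' relative densities; an SD below `sd_floor` is floored before the log so
#' that perfectly uniform profiles stay finite.
#'
#' @param profile a [positional_profile()] result (or any tibble with a
#'   `relative` column).
#' @param sd_floor floor for the standard deviation (default 1e-6).
#' @return a single real value.
#' @export
heterogeneity <- function(profile, sd_floor = 1e-6) {
  if (nrow(profile) < 3) abort_validation("need >= 3 included sections")
  log(max(stats::sd(profile$relative), sd_floor))
}

#' Classify longitudinal preference of a profile
#'
#' Spearman correlation of the relative density against the axis coordinate
#' (exact p for n <= 9 without ties, t-approximation otherwise): a
#' significantly positive correlation is "posterior", significantly
#' negative "anterior", otherwise "uniform". For species stored with a
#' reversed longitudinal convention, `reversed_axis = TRUE` flips the call
#' so that it is expressed in the primate anterior/posterior frame.
#'
#' @param profile a [positional_profile()] result.
#' @param alpha significance level (default 0.05).
#' @param reversed_axis flip the anterior/posterior call.
#' @return one-row tibble (preference, rho, p_value, n_sections).
#' @export
classify_preference <- function(profile, alpha = 0.05, reversed_axis = FALSE) {
  if (nrow(profile) < 5) abort_validation("need >= 5 sections")
  x <- profile$axis_mm
  y <- profile$relative
  if (stats::sd(y) == 0) {
    return(tibble::tibble(preference = "uniform", rho = 0, p_value = 1,
                          n_sections = nrow(profile)))
  }
  exact <- nrow(profile) <= 9 && !anyDuplicated(y) && !anyDuplicated(x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  pref <- if (ct$p.value < alpha && ct$estimate > 0) "posterior"
          else if (ct$p.value < alpha && ct$estimate < 0) "anterior"
          else "uniform"
  if (reversed_axis && pref != "uniform") {
    pref <- if (pref == "anterior") "posterior" else "anterior"
  }
  tibble::tibble(preference = pref, rho = unname(ct$estimate),
                 p_value = ct$p.value, n_sections = nrow(profile))
}

#' Dominant subregion of a cell type
#'
#' Returns the subregion with the largest occupancy fraction iff that
#' fraction strictly exceeds 0.4, otherwise `NA` ("no dominant subregion").
#'
#' @param fractions named non-negative fractions summing to at most 1.
#' @param threshold dominance threshold (default 0.4, strict).
#' @return the dominant subregion name or `NA_character_`.
#' @export
subregion_dominance <- function(fractions, threshold = 0.4) {
  if (any(fractions < 0)) abort_validation("negative fraction")
  if (sum(fractions) > 1 + 1e-6) abort_validation("fractions sum to > 1")
  i <- which.max(fractions)
  if (fractions[i] > threshold) names(fractions)[i] else NA_character_
}

#' Gene-family score along the longitudinal axis
#'
#' Per section: the summed raw counts of the family genes over the masked
#' cells, divided by the total counts of those cells, then z-scored across
#' the included sections (mean 0, SD 1, ddof = 1). Sections without masked
#' cells are excluded and flagged.
#'
#' @param counts raw count matrix.
#' @param cells spatial cell table aligned with the matrix columns.
#' @param mask logical vector or cell-id vector selecting the cells to
#'   aggregate (e.g. CA1-registered cells).
#' @param family_genes family gene list (e.g. an HCN-like panel).
#' @return tibble of class `hipp_axis_profile` (section_id, axis_mm,
#'   fraction, z) with attribute `excluded_sections`.
#' @export
gene_family_score <- function(counts, cells, mask, family_genes) {
  missing <- setdiff(family_genes, rownames(counts))
  if (length(missing)) abort_validation("family genes absent: %s", paste(missing, collapse = ", "))
  if (is.logical(mask)) mask <- colnames(counts)[mask]
  idx <- match(mask, colnames(counts))
  sec <- cells$section_id[match(mask, cells$cell_id)]
  axis <- cells$axis_mm[match(mask, cells$cell_id)]
  fam <- Matrix::colSums(counts[family_genes, idx, drop = FALSE])
  tot <- Matrix::colSums(counts[, idx, drop = FALSE])
  all_sections <- dplyr::distinct(cells[cells$modality == "spatial",
                                        c("section_id", "axis_mm")])
  tab <- tibble::tibble(section_id = sec, axis_mm = axis, fam = fam, tot = tot) |>
    dplyr::group_by(.data$section_id, .data$axis_mm) |>
    dplyr::summarise(fraction = sum(.data$fam) / sum(.data$tot), .groups = "drop") |>
    dplyr::arrange(.data$axis_mm)
  excluded <- setdiff(all_sections$section_id, tab$section_id)
  if (nrow(tab) < 3) abort_validation("need >= 3 sections with masked cells")
  tab$z <- as.numeric(scale(tab$fraction))
  if (all(is.nan(tab$z))) tab$z <- rep(0, nrow(tab))
  out <- tibble::new_tibble(tab, class = "hipp_axis_profile")
  attr(out, "entity") <- paste(family_genes, collapse = "+")
  attr(out, "coordinate") <- "axis"
  attr(out, "excluded_sections") <- excluded
  out
}

#' Test a profile for a U-shaped longitudinal trend
#'
#' Ordinary least squares of the profile value on the normalized axis
#' position and its square; U-shape requires a positive quadratic
#' coefficient with two-sided p below `alpha` and an interior vertex
#' (`-b / 2c` within (0.2, 0.8) of the normalized axis).
#'
#' @param profile tibble with `axis_mm` and a value column.
#' @param value name of the value column (default: `z` if present, else
#'   `relative`).
#' @param alpha significance level (default 0.05).
#' @return one-row tibble (ushape, curvature, p_value, vertex).
#' @export
ushape_test <- function(profile, value = NULL, alpha = 0.05) {
  if (nrow(profile) < 6) abort_validation("need >= 6 sections")
  value <- value %||% if ("z" %in% names(profile)) "z" else "relative"
  y <- profile[[value]]
  rng <- range(profile$axis_mm)
  if (diff(rng) == 0) abort_validation("collinear design: all axis positions equal")
  a <- (profile$axis_mm - rng[1]) / diff(rng)
  fit <- stats::lm(y ~ a + I(a^2))
  cf <- stats::coef(fit)
  curv <- unname(cf[3])
  sm <- suppressWarnings(summary(fit))  # exact fits are handled below
  sigma2 <- sm$sigma^2
  p <- if (is.finite(sigma2) && sigma2 > 1e-12) {
    sm$coefficients["I(a^2)", "Pr(>|t|)"]
  } else if (abs(curv) > 1e-8) 0 else 1
  vertex <- if (abs(curv) > 1e-12) -unname(cf[2]) / (2 * curv) else NA_real_
  tibble::tibble(ushape = isTRUE(curv > 0 && p < alpha &&
                                   !is.na(vertex) && vertex > 0.2 && vertex < 0.8),
                 curvature = curv, p_value = p, vertex = vertex)
}

#' Cluster cells on an ion-channel gene panel
#'
#' Restricts the normalized matrix to the panel genes and the masked cells
#' (e.g. CA1-registered cells), embeds with PCA and clusters at a coarse
#' default resolution suited to panel-level programs. Per-cluster
#' longitudinal profiles are emitted alongside the labels.
#'
#' @param nm spatial normalized matrix.
#' @param cells spatial cell table aligned with the matrix columns.
#' @param mask logical vector or cell ids selecting cells.
#' @param panel panel gene list.
#' @param resolution clustering resolution (default 0.3; panel programs are
#'   few and coarse).
#' @param k_neighbors,seed clustering parameters.
#' @return list with `clusters` (`hipp_clusters`) and `profiles` (tibble:
#'   cluster, section_id, axis_mm, n, relative, mean_axis_mm per cluster).
#' @export
channel_panel_clusters <- function(nm, cells, mask, panel, resolution = 0.3,
                                   k_neighbors = 15, seed = 1L) {
  missing <- setdiff(panel, rownames(nm))
  if (length(missing)) abort_validation("panel genes absent: %s", paste(missing, collapse = ", "))
  if (is.logical(mask)) mask <- colnames(nm)[mask]
  if (!length(mask)) abort_validation("empty cell mask")
  sub <- nm[panel, mask, drop = FALSE]
  v <- row_vars(sub)
  sub <- sub[v > 0, , drop = FALSE]
  if (nrow(sub) < 2) abort_degenerate("panel has fewer than 2 varying genes")
  emb <- embed_pca(sub, n_components = min(10, nrow(sub) - 1))
  cl <- cluster_cells(emb, k_neighbors = k_neighbors, resolution = resolution, seed = seed)
  meta <- cells[match(mask, cells$cell_id), ]
  prof <- tibble::tibble(cluster = cl$labels[mask],
                         section_id = meta$section_id, axis_mm = meta$axis_mm) |>
    dplyr::count(.data$cluster, .data$section_id, .data$axis_mm, name = "n") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(relative = .data$n / sum(.data$n),
                  mean_axis_mm = sum(.data$axis_mm * .data$n) / sum(.data$n)) |>
    dplyr::ungroup()
  list(clusters = cl, profiles = prof)
}
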