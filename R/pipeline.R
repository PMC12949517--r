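#' Pipeline configuration
#'
#' Assembles (and validates) the configuration that drives
#' [run_pipeline()]: synthetic-data scale, noise, clustering, registration,
#' homology and neighborhood parameters, plus the global seed. A YAML file
#' with the same (possibly partial) structure can be supplied; unknown keys
#' are rejected.
#'
#' @param path optional YAML file with overrides.
#' @param ... named overrides applied after the file (same key structure).
#' @return a validated config list of class `hipp_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    seed = 1L,
    species = c("macaque", "marmoset", "mouse"),
    n_genes = 1500,
    n_reference_cells = 3000,
    n_sections = 8,
    n_cells_per_section = 600,
    capture_rate = 0.35,
    noise = list(dispersion = 0.15, library_meanlog = log(2500),
                 library_sdlog = 0.35, species_effect_sd = 0.08),
    clustering = list(n_components = 30, k_neighbors = 15, resolution = 1.0),
    consensus = list(resolutions = c(0.6, 1.0, 1.4), n_seeds = 5),
    registration = list(c_min = 0.1, n_hvgs = 2000),
    segmentation = list(k_spatial = 10, resolution = 0.2, n_components = 10),
    thresholds = list(tau_specific = 0.1, tau_match = 0.3, dominance = 0.4,
                      alpha = 0.05),
    neighborhood = list(radius_um = 50, n_perm = 1000, min_cells = 10))
  merge_cfg <- function(base, over, prefix = "") {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) abort_validation("unknown config keys: %s",
                                      paste0(prefix, bad, collapse = ", "))
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]], paste0(prefix, k, "."))
      } else over[[k]]
    }
    base
  }
  cfg <- defaults
  if (!is.null(path)) cfg <- merge_cfg(cfg, yaml::read_yaml(path))
  cfg <- merge_cfg(cfg, list(...))
  structure(cfg, class = c("hipp_config", "list"))
}

pipeline_stages <- c("simulate", "cluster_reference", "segment", "register",
                     "cross_species", "axis", "neighborhood", "report")

need_stage <- function(res, what, for_stage) {
  if (is.null(res[[what]])) {
    rlang::abort(sprintf("stage '%s' requires stage '%s' to have run", for_stage, what),
                 class = "hippatlas_dependency_error")
  }
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the staged analysis on synthetic data: simulation of reference
#' and spatial datasets per species, pooled reference clustering with
#' hierarchy annotation, per-section subregion segmentation with
#' cross-section matching and panel annotation, label transfer onto spatial
#' cells, cross-species consensus co-clustering with primate-specific
#' calls, longitudinal axis statistics, neighborhood enrichment, and a
#' summary report. Every stochastic stage consumes a seed derived
#' deterministically from the global seed and the stage name. When `outdir`
#' is given, stage outputs are written as TSV/JSON with a provenance file
#' recording all parameters.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run ("all" or a subset of
#'   `simulate`, `cluster_reference`, `segment`, `register`,
#'   `cross_species`, `axis`, `neighborhood`, `report`); dependencies must
#'   have run (they are included automatically when `stages = "all"`).
#' @param outdir optional output directory.
#' @param results optionally, a previous result list to extend (for staged
#'   invocation).
#' @return named list of stage results; `$report` holds the aggregate
#'   summary.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         outdir = NULL, results = list()) {
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort_validation("unknown stages: %s", paste(bad, collapse = ", "))
  seed <- config$seed
  tax <- default_taxonomy(config$n_genes)
  noise <- do.call(noise_params, config$noise)
  res <- results

  log_stage <- function(name) message(sprintf("[hippatlas] stage %s", name))

  if ("simulate" %in% stages) {
    log_stage("simulate")
    res$simulate <- lapply(stats::setNames(config$species, config$species), function(sp) {
      ref <- simulate_reference(tax, sp, config$n_reference_cells, noise,
                                seed = derive_seed(seed, paste0("ref:", sp)))
      spe <- simulate_sections(
        tax, sp, default_section_specs(sp, config$n_sections, config$n_cells_per_section),
        capture_rate = config$capture_rate, noise = noise,
        seed = derive_seed(seed, paste0("spatial:", sp)))
      list(reference = ref, spatial = spe,
           nm_ref = normalize_log_cp10k(ref$expr),
           nm_spatial = normalize_log_cp10k(spe$expr))
    })
    res$taxonomy <- tax
  }

  if ("cluster_reference" %in% stages) {
    need_stage(res, "simulate", "cluster_reference")
    log_stage("cluster_reference")
    nm_all <- do.call(cbind, lapply(res$simulate, function(s) s$nm_ref))
    hvgs <- select_hvgs(nm_all, min(2000, nrow(nm_all)))
    emb <- embed_pca(nm_all[hvgs, ], n_components = config$clustering$n_components)
    cl <- cluster_cells(emb, k_neighbors = config$clustering$k_neighbors,
                        resolution = config$clustering$resolution,
                        seed = derive_seed(seed, "cluster_reference"))
    ann <- annotate_clusters(nm_all, cl, tax)
    res$cluster_reference <- list(clusters = cl, annotation = ann,
                                  subclass_counts = count_subclasses(ann))
  }

  if ("segment" %in% stages) {
    need_stage(res, "simulate", "segment")
    log_stage("segment")
    res$segment <- lapply(stats::setNames(config$species, config$species), function(sp) {
      s <- res$simulate[[sp]]
      secs <- unique(s$spatial$cells$section_id)
      maps <- lapply(secs, function(sec) {
        idx <- s$spatial$cells$section_id == sec
        segment_section(s$nm_spatial[, idx, drop = FALSE],
                        s$spatial$cells[idx, c("x_um", "y_um")],
                        k_spatial = config$segmentation$k_spatial,
                        n_components = config$segmentation$n_components,
                        resolution = config$segmentation$resolution,
                        seed = derive_seed(seed, paste0("segment:", sec)),
                        section_id = sec)
      })
      matching <- match_subregions_across_sections(maps)
      maps <- lapply(maps, function(m) {
        idx <- names(m$labels)
        annotate_subregions(m, s$nm_spatial[, idx, drop = FALSE],
                            default_marker_panel(tax),
                            seed = derive_seed(seed, "annotate"))
      })
      list(maps = maps, matching = matching)
    })
  }

  if ("register" %in% stages) {
    need_stage(res, "simulate", "register")
    log_stage("register")
    res$register <- lapply(stats::setNames(config$species, config$species), function(sp) {
      s <- res$simulate[[sp]]
      types <- stats::setNames(s$reference$truth$cells$type, s$reference$truth$cells$cell_id)
      hvgs <- select_hvgs(s$nm_ref, min(config$registration$n_hvgs, nrow(s$nm_ref)))
      cent <- type_centroids(s$nm_ref, types, hvgs)
      tr <- transfer_labels(s$nm_spatial, cent, c_min = config$registration$c_min)
      truth <- s$spatial$truth$cells
      acc <- mean(tr$cell_type == truth$type[match(tr$cell_id, truth$cell_id)])
      comp <- tibble::tibble(cell_type = tr$cell_type,
                             subregion = truth$subregion[match(tr$cell_id, truth$cell_id)]) |>
        dplyr::count(.data$cell_type, .data$subregion) |>
        dplyr::group_by(.data$cell_type) |>
        dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
        dplyr::ungroup()
      list(centroids = cent, transfer = tr, accuracy = acc, composition = comp)
    })
  }

  if ("cross_species" %in% stages) {
    need_stage(res, "simulate", "cross_species")
    log_stage("cross_species")
    glut <- lapply(res$simulate, function(s) {
      truth <- s$reference$truth$cells
      keep <- truth$class == "glutamatergic"
      list(nm = s$nm_ref[, keep, drop = FALSE],
           types = stats::setNames(truth$type[keep], truth$cell_id[keep]))
    })
    n_seeds <- config$consensus$n_seeds
    hpair <- function(a, b) homology_matrix(
      glut[[a]]$nm, glut[[a]]$types, glut[[b]]$nm, glut[[b]]$types,
      resolutions = config$consensus$resolutions,
      seeds = derive_seed(seed, paste(a, b, sep = ":")) %% 10000L + seq_len(n_seeds),
      tau_match = config$thresholds$tau_match)
    hm_mac_mou <- hpair("macaque", "mouse")
    hm_mar_mou <- hpair("marmoset", "mouse")
    hm_mac_mar <- hpair("macaque", "marmoset")
    primate <- call_primate_specific(hm_mac_mou, hm_mar_mou, hm_mac_mar,
                                     tau_specific = config$thresholds$tau_specific,
                                     tau_match = config$thresholds$tau_match)
    comp <- composition_stats(dplyr::bind_rows(lapply(res$simulate, function(s)
      s$reference$truth$cells)))
    res$cross_species <- list(macaque_mouse = hm_mac_mou, marmoset_mouse = hm_mar_mou,
                              macaque_marmoset = hm_mac_mar,
                              primate_specific = primate, composition = comp)
  }

  if ("axis" %in% stages) {
    need_stage(res, "simulate", "axis")
    need_stage(res, "register", "axis")
    log_stage("axis")
    res$axis <- lapply(stats::setNames(config$species, config$species), function(sp) {
      s <- res$simulate[[sp]]
      tr <- res$register[[sp]]$transfer
      cells <- s$spatial$cells
      cells$cell_type <- tr$cell_type[match(cells$cell_id, tr$cell_id)]
      rev_ax <- unname(tax$reversed_axis[[sp]])
      glut_types <- types_present(tax, sp)
      glut_types <- glut_types$type[glut_types$class == "glutamatergic"]
      prof_tbl <- purrr::map_dfr(glut_types, function(t) {
        p <- positional_profile(cells, t, "axis")
        if (attr(p, "absent") || nrow(p) < 3) return(NULL)
        pref <- if (nrow(p) >= 5) {
          classify_preference(p, alpha = config$thresholds$alpha,
                              reversed_axis = rev_ax)
        } else {
          tibble::tibble(preference = NA_character_, rho = NA_real_,
                         p_value = NA_real_, n_sections = nrow(p))
        }
        cbind(tibble::tibble(cell_type = t, heterogeneity = heterogeneity(p)), pref)
      })
      ca1 <- cells$cell_id[!is.na(cells$cell_type) &
                             cells$cell_type %in% c("Glu CA1-1", "Glu CA1-2")]
      fam <- gene_family_score(s$spatial$expr, cells, ca1, tax$families$HCN_like)
      us <- if (nrow(fam) >= 6) ushape_test(fam) else NULL
      list(profiles = prof_tbl, hcn_score = fam, ushape = us)
    })
  }

  if ("neighborhood" %in% stages) {
    need_stage(res, "simulate", "neighborhood")
    need_stage(res, "register", "neighborhood")
    log_stage("neighborhood")
    sp <- config$species[1]
    s <- res$simulate[[sp]]
    tr <- res$register[[sp]]$transfer
    cells <- s$spatial$cells
    cells$cell_type <- tr$cell_type[match(cells$cell_id, tr$cell_id)]
    nh <- purrr::map_dfr(unique(cells$section_id), function(sec) {
      idx <- cells$section_id == sec
      nhood_enrichment(cells[idx, c("x_um", "y_um")], cells$cell_type[idx],
                       radius_um = config$neighborhood$radius_um,
                       n_perm = config$neighborhood$n_perm,
                       min_cells = config$neighborhood$min_cells,
                       seed = derive_seed(seed, paste0("nhood:", sec)),
                       section_id = sec)
    })
    axis_map <- dplyr::distinct(cells[, c("section_id", "axis_mm")])
    nh$axis_mm <- axis_map$axis_mm[match(nh$section, axis_map$section_id)]
    trends <- nh |>
      dplyr::group_by(.data$type_a, .data$type_b) |>
      dplyr::group_modify(~ axis_trend(.x)) |>
      dplyr::ungroup()
    res$neighborhood <- list(species = sp, scores = nh, trends = trends)
  }

  if ("report" %in% stages) {
    for (st in c("cluster_reference", "cross_species", "axis", "neighborhood")) {
      need_stage(res, st, "report")
    }
    log_stage("report")
    prof1 <- res$axis[[config$species[1]]]$profiles
    het_rank <- if (nrow(prof1)) dplyr::arrange(prof1, dplyr::desc(.data$heterogeneity)) else prof1
    res$report <- list(
      subclass_counts = res$cluster_reference$subclass_counts,
      primate_specific = res$cross_species$primate_specific,
      composition = res$cross_species$composition,
      preference = lapply(res$axis, function(a)
        a$profiles[, c("cell_type", "preference", "rho", "p_value")]),
      heterogeneity_ranking = if (nrow(het_rank)) het_rank[, c("cell_type", "heterogeneity")] else het_rank,
      ushape = lapply(res$axis, function(a) a$ushape),
      neighborhood_trends = res$neighborhood$trends,
      seed = seed)
  }

  if (!is.null(outdir)) write_pipeline_outputs(res, config, outdir, stages)
  res
}

write_pipeline_outputs <- function(res, config, outdir, stages) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(parameters = unclass(config), stages = stages,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               content_hash = rlang::hash(lapply(res$simulate, function(s)
                 list(dim(s$reference$expr), dim(s$spatial$expr)))))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$cluster_reference)) {
    readr::write_tsv(res$cluster_reference$annotation,
                     file.path(outdir, "reference_cluster_annotation.tsv"))
  }
  if (!is.null(res$cross_species)) {
    M <- res$cross_species$macaque_mouse$matrix
    readr::write_tsv(tibble::as_tibble(M, rownames = "type_a"),
                     file.path(outdir, "homology_macaque_mouse.tsv"))
    jsonlite::write_json(res$cross_species$primate_specific,
                         file.path(outdir, "primate_specific.json"))
  }
  if (!is.null(res$axis)) {
    readr::write_tsv(dplyr::bind_rows(lapply(res$axis, function(a) a$profiles),
                                      .id = "species"),
                     file.path(outdir, "axis_profiles.tsv"))
  }
  if (!is.null(res$neighborhood)) {
    readr::write_tsv(res$neighborhood$scores, file.path(outdir, "neighborhood_scores.tsv"))
  }
  if (!is.null(res$report)) {
    jsonlite::write_json(
      list(subclass_counts = res$report$subclass_counts,
           primate_specific = res$report$primate_specific,
           seed = res$report$seed),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}
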