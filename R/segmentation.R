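#' Spatially smooth expression profiles within a section
#'
#' Replaces each cell's profile by the unweighted mean over itself and its
#' `k_spatial` nearest spatial neighbours (Euclidean distance in microns).
#' `k_spatial = 0` is the identity.
#'
#' @param nm normalized gene-by-cell matrix for one section.
#' @param coords two-column matrix/data frame of x/y positions (microns),
#'   rows aligned with the matrix columns.
#' @param k_spatial neighbours to average over (default 10).
#' @return smoothed matrix of the same shape.
#' @export
spatial_smooth <- function(nm, coords, k_spatial = 10) {
  coords <- as.matrix(coords[, 1:2])
  if (nrow(coords) != ncol(nm)) abort_validation("coords rows must match matrix columns")
  if (k_spatial == 0) return(nm)
  if (k_spatial + 1 > ncol(nm)) {
    abort_validation("section has %d cells; need > k_spatial (%d)", ncol(nm), k_spatial)
  }
  nn <- knn_indices(coords, k_spatial)
  n <- ncol(nm)
  # sparse averaging operator: column j averages cell j and its neighbours
  w <- Matrix::sparseMatrix(i = c(seq_len(n), as.vector(nn)),
                            j = c(seq_len(n), rep(seq_len(n), k_spatial)),
                            x = 1 / (k_spatial + 1), dims = c(n, n))
  out <- nm %*% w
  dimnames(out) <- dimnames(nm)
  methods::as(out, "CsparseMatrix")
}

#' Segment one spatial section into transcriptome-defined subregions
#'
#' Pipeline: spatial smoothing, PCA embedding, graph community detection.
#' Clusters under `min_frac_section` of the section's cells are merged into
#' the spatially adjacent cluster (sharing at least one spatial
#' nearest-neighbour edge) with the highest centroid Pearson correlation.
#' Each cluster carries a centroid profile and its top-50 marker set
#' (largest centroid-minus-section-mean difference), used for cross-section
#' matching.
#'
#' @param nm normalized gene-by-cell matrix for the section.
#' @param coords x/y positions in microns.
#' @param k_spatial smoothing neighbourhood (default 10).
#' Smoothed profiles are embedded without per-gene standardization: subregion
#' programs differ in overall magnitude and standardizing dilutes that
#' band-level signal with per-gene noise.
#' @param n_components,k_neighbors,resolution,seed clustering parameters.
#' @param min_frac_section minimum cluster size as a fraction of section
#'   cells (default 0.01).
#' @param section_id optional label stored in the map.
#' @return object of class `hipp_subregion_map`: labels, centroids, top-50
#'   marker sets, annotation (NULL until [annotate_subregions()]).
#' @export
segment_section <- function(nm, coords, k_spatial = 10, n_components = 10,
                            k_neighbors = 15, resolution = 0.2, seed = 1L,
                            min_frac_section = 0.01, section_id = NA_character_) {
  if (ncol(nm) < 100) abort_validation("section needs >= 100 cells (got %d)", ncol(nm))
  coords <- as.matrix(coords[, 1:2])
  sm <- spatial_smooth(nm, coords, k_spatial)
  emb <- embed_pca(sm, n_components = n_components, standardize = FALSE)
  cl <- cluster_cells(emb, k_neighbors = k_neighbors, resolution = resolution, seed = seed)
  labels <- cl$labels
  nn_sp <- knn_indices(coords, min(10, ncol(nm) - 1))

  centroid_of <- function(lab, ids) {
    vapply(ids, function(l) Matrix::rowMeans(sm[, lab == l, drop = FALSE]), numeric(nrow(sm)))
  }
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_frac_section * ncol(nm) & sizes < max(sizes)]
    if (!length(small)) break
    ids <- names(sizes)
    cent <- centroid_of(labels, ids)
    s <- small[1]
    sidx <- which(labels == as.integer(s))
    adj <- unique(labels[as.vector(nn_sp[sidx, ])])
    adj <- setdiff(as.character(adj), s)
    if (!length(adj)) adj <- setdiff(ids, s)
    cors <- stats::cor(cent[, s], cent[, adj, drop = FALSE])[1, ]
    labels[sidx] <- as.integer(adj[which.max(cors)])
  }
  ids <- names(sort(table(labels), decreasing = TRUE))
  labels <- stats::setNames(stats::setNames(seq_along(ids) - 1L, ids)[as.character(labels)],
                            names(cl$labels))
  cent <- centroid_of(labels, as.character(sort(unique(labels))))
  overall <- Matrix::rowMeans(sm)
  markers <- lapply(seq_len(ncol(cent)), function(j) {
    d <- cent[, j] - overall
    rownames(sm)[order(-d, rownames(sm), method = "radix")][1:50]
  })
  names(markers) <- colnames(cent)
  structure(list(section_id = section_id, labels = labels, centroids = cent,
                 markers = markers, n_cells = length(labels),
                 annotation = NULL,
                 parameters = list(k_spatial = k_spatial, resolution = resolution,
                                   seed = seed, min_frac_section = min_frac_section)),
            class = "hipp_subregion_map")
}

#' @export
print.hipp_subregion_map <- function(x, ...) {
  cat("<hipp_subregion_map> section ", x$section_id, ": ",
      ncol(x$centroids), " subregion clusters over ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Jaccard index of two sets
#'
#' @param a,b vectors treated as sets.
#' @return |intersection| / |union|.
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Match subregion clusters across sections
#'
#' The section with the most cells is the reference. Every other section's
#' clusters are matched one-to-one to the reference clusters by the optimal
#' assignment maximizing centroid Pearson correlation (maximum-weight
#' bipartite matching). Consistency of a matched pair is the Jaccard index
#' of the two clusters' top-50 marker sets. Clusters without a counterpart
#' are reported as unmatched, not dropped.
#'
#' @param maps list of `hipp_subregion_map` (>= 2).
#' @return list with `reference_section`, `correspondence` (tibble: section,
#'   cluster, ref_cluster, correlation, jaccard; unmatched clusters have NA
#'   ref_cluster) and `section_consistency` (tibble: section, mean_jaccard).
#' @export
match_subregions_across_sections <- function(maps) {
  if (length(maps) < 2) abort_validation("need >= 2 sections")
  sizes <- vapply(maps, function(m) m$n_cells, numeric(1))
  # reference = section with most cells; ties break toward the middle of the
  # series so the reference sits centrally along the axis
  cand <- which(sizes == max(sizes))
  ref <- maps[[cand[which.min(abs(cand - (length(maps) + 1) / 2))]]]
  rows <- list()
  for (m in maps) {
    if (identical(m$section_id, ref$section_id)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = m$section_id, cluster = colnames(m$centroids),
        ref_cluster = colnames(m$centroids), correlation = 1,
        jaccard = 1)
      next
    }
    cors <- stats::cor(m$centroids, ref$centroids)
    n1 <- ncol(m$centroids); n2 <- ncol(ref$centroids)
    g <- igraph::graph_from_biadjacency_matrix(matrix(TRUE, n1, n2), weighted = TRUE)
    igraph::E(g)$weight <- as.vector(t(cors)) + 10  # cardinality dominates
    mt <- igraph::max_bipartite_match(g)$matching
    match_idx <- mt[seq_len(n1)]
    ref_j <- ifelse(is.na(match_idx), NA_integer_, as.integer(match_idx) - n1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      section = m$section_id,
      cluster = colnames(m$centroids),
      ref_cluster = ifelse(is.na(ref_j), NA_character_, colnames(ref$centroids)[ref_j]),
      correlation = ifelse(is.na(ref_j), NA_real_, cors[cbind(seq_len(n1), ref_j)]),
      jaccard = vapply(seq_len(n1), function(i) {
        if (is.na(ref_j[i])) return(NA_real_)
        jaccard_index(m$markers[[i]], ref$markers[[ref_j[i]]])
      }, numeric(1)))
  }
  corr <- dplyr::bind_rows(rows)
  cons <- corr |>
    dplyr::filter(.data$section != ref$section_id, !is.na(.data$jaccard)) |>
    dplyr::group_by(.data$section) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard), .groups = "drop")
  list(reference_section = ref$section_id, correspondence = corr,
       section_consistency = cons)
}

#' Annotate subregion clusters with a named marker panel
#'
#' Each cluster is assigned the panel name with the highest mean module
#' score of the panel's genes over the cluster's cells; when the best score
#' does not exceed the runner-up by at least `tau_annot` the cluster is
#' labelled "unassigned".
#'
#' @param map a `hipp_subregion_map`.
#' @param nm the section's normalized matrix (same cells).
#' @param marker_panel named list: subregion name -> gene vector.
#' @param tau_annot required margin over the runner-up (default 0.1).
#' @param seed seed for the module-score control draw.
#' @return the map with `annotation` set (named character, cluster ->
#'   subregion name or "unassigned").
#' @export
annotate_subregions <- function(map, nm, marker_panel, tau_annot = 0.1, seed = 1L) {
  if (!length(marker_panel)) abort_validation("empty marker panel")
  panel <- lapply(marker_panel, intersect, rownames(nm))
  bad <- names(panel)[lengths(panel) == 0]
  if (length(bad)) abort_validation("panel genes absent from matrix for: %s",
                                    paste(bad, collapse = ", "))
  nm <- nm[, names(map$labels), drop = FALSE]
  scores <- vapply(panel, function(gs) module_score(nm, gs, seed = seed)$score,
                   numeric(ncol(nm)))
  cl_ids <- sort(unique(map$labels))
  ann <- vapply(cl_ids, function(cl) {
    s <- colMeans(scores[map$labels == cl, , drop = FALSE])
    ord <- order(-s)
    best <- s[ord[1]]
    runner <- if (length(s) > 1) s[ord[2]] else -Inf
    if (best - runner < tau_annot) "unassigned" else names(s)[ord[1]]
  }, character(1))
  map$annotation <- stats::setNames(ann, as.character(cl_ids))
  map
}
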