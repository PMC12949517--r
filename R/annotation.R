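#' Annotate clusters into the taxonomy hierarchy
#'
#' Maps each cluster onto the taxonomy's subclass level by marker scoring:
#' the cluster centroid (mean log-normalized expression) is z-scored across
#' genes and each subclass receives the mean z over its marker program; the
#' cluster is assigned the top-scoring subclass, which fixes its class.
#' Several clusters may map to the same subclass (over-clustering is
#' harmless at this level); the number of distinct subclasses recovered per
#' class is the hierarchy-recovery summary.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param clusters a `hipp_clusters` or named cell -> cluster vector.
#' @param tax a `hipp_taxonomy`.
#' @return tibble (cluster, n_cells, subclass, class, score, margin).
#' @export
annotate_clusters <- function(nm, clusters, tax) {
  g <- resolve_groups(nm, clusters)
  cl_ids <- sort(unique(g[!is.na(g)]))
  marker_sets <- stats::setNames(lapply(tax$subclasses$markers, function(m) {
    intersect(names(m), rownames(nm))
  }), tax$subclasses$subclass)
  if (any(lengths(marker_sets) == 0)) {
    abort_validation("taxonomy subclass markers absent from matrix")
  }
  purrr::map_dfr(cl_ids, function(cl) {
    idx <- which(g == cl)
    cent <- Matrix::rowMeans(nm[, idx, drop = FALSE])
    z <- (cent - mean(cent)) / stats::sd(cent)
    s <- vapply(marker_sets, function(gs) mean(z[gs]), numeric(1))
    ord <- order(-s)
    sc <- names(s)[ord[1]]
    tibble::tibble(cluster = cl, n_cells = length(idx), subclass = sc,
                   class = tax$subclasses$class[match(sc, tax$subclasses$subclass)],
                   score = s[ord[1]], margin = s[ord[1]] - s[ord[2]])
  })
}

#' Count recovered subclasses per class
#'
#' @param annotation an [annotate_clusters()] table.
#' @return tibble (class, n_subclasses) of distinct subclasses recovered.
#' @export
count_subclasses <- function(annotation) {
  annotation |>
    dplyr::distinct(.data$class, .data$subclass) |>
    dplyr::count(.data$class, name = "n_subclasses")
}
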