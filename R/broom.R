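# tidy()/glance() methods for the fitted result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hipp_clusters <- function(x, ...) {
  tibble::tibble(cell_id = names(x$labels), cluster = unname(x$labels))
}

#' @export
glance.hipp_clusters <- function(x, ...) {
  tibble::tibble(n_cells = length(x$labels),
                 n_clusters = length(unique(x$labels)),
                 k_neighbors = x$parameters$k_neighbors,
                 resolution = x$parameters$resolution,
                 seed = x$parameters$seed)
}

#' @export
tidy.hipp_homology <- function(x, ...) {
  M <- x$matrix
  tidyr::expand_grid(type_a = rownames(M), type_b = colnames(M)) |>
    dplyr::mutate(proportion = as.vector(t(M)))
}

#' @export
glance.hipp_homology <- function(x, ...) {
  tibble::tibble(n_types_a = nrow(x$matrix), n_types_b = ncol(x$matrix),
                 n_runs = length(x$parameters$resolutions) * length(x$parameters$seeds),
                 n_matched = sum(x$calls$matched),
                 n_unmatched = sum(!x$calls$matched))
}

#' @export
tidy.hipp_subregion_map <- function(x, ...) {
  ann <- if (!is.null(x$annotation)) x$annotation[as.character(x$labels)] else NA_character_
  tibble::tibble(cell_id = names(x$labels), cluster = unname(x$labels),
                 subregion = unname(ann))
}

#' @export
glance.hipp_subregion_map <- function(x, ...) {
  tibble::tibble(section_id = x$section_id, n_cells = x$n_cells,
                 n_clusters = ncol(x$centroids),
                 n_annotated = if (is.null(x$annotation)) 0L else
                   sum(x$annotation != "unassigned"))
}

#' @export
tidy.hipp_centroids <- function(x, ...) {
  tibble::as_tibble(t(x$profiles), rownames = "cell_type")
}
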