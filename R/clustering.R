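#' Principal-component embedding of a normalized matrix
#'
#' Computes principal components of the (optionally per-gene standardized)
#' log-normalized values across cells via the eigen-decomposition of the
#' gene-gene covariance. Deterministic: the sign of each component is fixed
#' so that its largest-magnitude gene loading is positive. Genes with zero
#' variance are dropped before standardization.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param n_components number of components (default 30).
#' @param standardize scale genes to unit variance before the decomposition.
#' @return object of class `hipp_embedding`: list with `coords` (cells x
#'   components, rownames = cell ids) and `explained_variance`.
#' @export
embed_pca <- function(nm, n_components = 30, standardize = TRUE) {
  v <- row_vars(nm)
  keep <- v > 0
  if (!any(keep)) abort_degenerate("matrix is constant; no principal components")
  n_components <- min(n_components, sum(keep), ncol(nm) - 1)
  if (n_components < 1) abort_validation("n_components must be >= 1 and < min(genes, cells)")
  x <- t(as.matrix(nm[keep, , drop = FALSE]))          # cells x genes
  x <- scale(x, center = TRUE, scale = if (standardize) sqrt(v[keep]) else FALSE)
  cv <- crossprod(x) / (nrow(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  k <- seq_len(n_components)
  load <- eig$vectors[, k, drop = FALSE]
  for (j in k) {                                       # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  coords <- x %*% load
  rownames(coords) <- colnames(nm)
  colnames(coords) <- sprintf("PC%d", k)
  structure(list(coords = coords,
                 explained_variance = pmax(eig$values[k], 0),
                 total_variance = sum(pmax(eig$values, 0))),
            class = "hipp_embedding")
}

#' Graph community detection on an embedding
#'
#' Builds an undirected unit-weight k-nearest-neighbour graph (Euclidean in
#' the embedding) and partitions it with modularity-based Leiden community
#' detection at the given resolution. Reproducible from `seed`. Clusters
#' smaller than `min_size` are merged into the cluster with the nearest
#' centroid. Cluster ids are contiguous integers from 0, ordered by
#' decreasing size.
#'
#' @param emb a `hipp_embedding` (or a bare cells x dims matrix).
#' @param k_neighbors neighbours per cell (default 15).
#' @param resolution modularity resolution (default 1.0).
#' @param seed integer seed.
#' @param min_size minimum cluster size before merging (default 10).
#' @return object of class `hipp_clusters`: list with `labels` (named
#'   integer vector, cell id -> cluster) and `parameters`.
#' @export
cluster_cells <- function(emb, k_neighbors = 15, resolution = 1.0, seed = 1L,
                          min_size = 10) {
  coords <- if (inherits(emb, "hipp_embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (k_neighbors >= n) abort_validation("k_neighbors (%d) must be < n_cells (%d)", k_neighbors, n)
  nn <- knn_indices(coords, k_neighbors)
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 5)))
  memb <- as.integer(memb)
  # merge undersized clusters into the nearest cluster by centroid distance
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size & sizes < max(sizes)]
    if (!length(small)) break
    cent <- do.call(rbind, lapply(sort(unique(memb)), function(cl) {
      colMeans(coords[memb == cl, , drop = FALSE])
    }))
    rownames(cent) <- sort(unique(memb))
    s <- small[1]
    d <- colSums((t(cent) - cent[s, ])^2)
    d[s] <- Inf
    memb[memb == as.integer(s)] <- as.integer(names(which.min(d)))
  }
  # contiguous ids from 0, largest cluster first
  ord <- names(sort(table(memb), decreasing = TRUE))
  relab <- stats::setNames(seq_along(ord) - 1L, ord)
  labels <- stats::setNames(relab[as.character(memb)], rownames(coords))
  structure(list(labels = labels,
                 parameters = list(k_neighbors = k_neighbors,
                                   resolution = resolution, seed = seed,
                                   min_size = min_size)),
            class = "hipp_clusters")
}

#' @export
print.hipp_clusters <- function(x, ...) {
  cat("<hipp_clusters> ", length(unique(x$labels)), " clusters over ",
      length(x$labels), " cells (resolution ", x$parameters$resolution,
      ", seed ", x$parameters$seed, ")\n", sep = "")
  invisible(x)
}

#' Consensus clustering runs
#'
#' One clustering per (resolution, seed) pair, all on the same embedding of
#' the same matrix. The embedding itself is deterministic, so it is computed
#' once.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param resolutions numeric vector of resolutions.
#' @param seeds integer vector of seeds.
#' @param n_components,k_neighbors forwarded to [embed_pca()] /
#'   [cluster_cells()].
#' @return list of `hipp_clusters`, one per (resolution, seed) pair.
#' @export
consensus_runs <- function(nm, resolutions = c(0.6, 1.0, 1.4),
                           seeds = 1:5, n_components = 30, k_neighbors = 15) {
  if (!length(resolutions) || !length(seeds)) {
    abort_validation("resolutions and seeds must be non-empty")
  }
  emb <- embed_pca(nm, n_components = n_components)
  grid <- tidyr::expand_grid(resolution = resolutions, seed = as.integer(seeds))
  purrr::pmap(grid, function(resolution, seed) {
    cluster_cells(emb, k_neighbors = k_neighbors, resolution = resolution, seed = seed)
  })
}
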