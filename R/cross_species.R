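#' Consensus co-clustering homology matrix between two species
#'
#' Cells of both species are concatenated on shared highly variable genes
#' (the shared namespace stands in for a 1:1 ortholog mapping applied
#' upstream) and jointly clustered once per (resolution, seed) pair. For a
#' run with cluster sizes `n_{i,c}` (cells of species-A type i in joint
#' cluster c), the run's co-clustering proportion is
#' `P(i,j) = sum_c n_{i,c} * n_{j,c} / (n_i * n_j)` — the probability that a
#' random cell of type i and a random cell of type j land in the same joint
#' cluster. The homology matrix is the mean over runs; it lies in \[0, 1\]
#' and is invariant to cluster relabeling.
#'
#' @param nm_a,nm_b normalized matrices (shared gene namespace).
#' @param labels_a,labels_b cell typings.
#' @param resolutions consensus resolutions (default 0.6, 1.0, 1.4).
#' @param seeds consensus seeds (default 1:5).
#' @param n_hvgs joint highly-variable-gene depth (default 2000).
#' @param min_cells types with fewer cells are excluded with a warning.
#' @param tau_match best-match floor used for the per-row calls (default 0.3).
#' @return object of class `hipp_homology`: `matrix` (types A x types B),
#'   `calls` tibble (type_a, best_match, best_value, matched), run
#'   parameters.
#' @export
homology_matrix <- function(nm_a, labels_a, nm_b, labels_b,
                            resolutions = c(0.6, 1.0, 1.4), seeds = 1:5,
                            n_hvgs = 2000, min_cells = 5, tau_match = 0.3) {
  ga <- resolve_groups(nm_a, labels_a)
  gb <- resolve_groups(nm_b, labels_b)
  drop_small <- function(g, tag) {
    sz <- table(g)
    small <- names(sz)[sz < min_cells]
    if (length(small)) {
      warning(sprintf("excluding %s types with < %d cells: %s", tag, min_cells,
                      paste(small, collapse = ", ")), call. = FALSE)
      g[g %in% small] <- NA
    }
    g
  }
  ga <- drop_small(ga, "species-A")
  gb <- drop_small(gb, "species-B")
  shared <- intersect(rownames(nm_a), rownames(nm_b))
  if (!length(shared)) abort_validation("no shared genes")
  comb <- cbind(nm_a[shared, , drop = FALSE], nm_b[shared, , drop = FALSE])
  hvgs <- select_hvgs(comb, min(n_hvgs, length(shared)))
  runs <- consensus_runs(comb[hvgs, , drop = FALSE], resolutions = resolutions,
                         seeds = seeds)
  types_a <- sort(unique(ga[!is.na(ga)]))
  types_b <- sort(unique(gb[!is.na(gb)]))
  idx_a <- seq_len(ncol(nm_a))
  idx_b <- ncol(nm_a) + seq_len(ncol(nm_b))
  acc <- matrix(0, length(types_a), length(types_b), dimnames = list(types_a, types_b))
  for (run in runs) {
    cl <- run$labels
    acc <- acc + coclustering_proportion(ga, gb, cl[idx_a], cl[idx_b])
  }
  M <- acc / length(runs)
  best_j <- apply(M, 1, which.max)
  calls <- tibble::tibble(type_a = rownames(M),
                          best_match = colnames(M)[best_j],
                          best_value = M[cbind(seq_len(nrow(M)), best_j)],
                          matched = M[cbind(seq_len(nrow(M)), best_j)] >= tau_match)
  structure(list(matrix = M, calls = calls,
                 parameters = list(resolutions = resolutions, seeds = seeds,
                                   n_hvgs = n_hvgs, min_cells = min_cells,
                                   tau_match = tau_match)),
            class = "hipp_homology")
}

#' Co-clustering proportion matrix for one joint clustering
#'
#' `P(i, j) = sum_c n_{i,c} * n_{j,c} / (n_i * n_j)`: the probability that a
#' random cell of species-A type i and a random cell of species-B type j
#' fall in the same joint cluster. Invariant to cluster relabeling.
#'
#' @param types_a,types_b per-cell type labels of the two species.
#' @param clusters_a,clusters_b their joint-cluster assignments.
#' @return matrix (types A x types B) of proportions in \[0, 1\].
#' @export
coclustering_proportion <- function(types_a, types_b, clusters_a, clusters_b) {
  ta <- sort(unique(types_a[!is.na(types_a)]))
  tb <- sort(unique(types_b[!is.na(types_b)]))
  cls <- sort(unique(c(clusters_a, clusters_b)))
  tab_a <- table(factor(types_a, ta), factor(clusters_a, cls))
  tab_b <- table(factor(types_b, tb), factor(clusters_b, cls))
  n_a <- table(factor(types_a, ta))
  n_b <- table(factor(types_b, tb))
  P <- (tab_a %*% t(tab_b)) / (as.numeric(n_a) %o% as.numeric(n_b))
  dimnames(P) <- list(ta, tb)
  P
}

#' @export
print.hipp_homology <- function(x, ...) {
  cat("<hipp_homology> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " co-clustering proportions; ", sum(!x$calls$matched),
      " unmatched rows\n", sep = "")
  invisible(x)
}

#' Species-specific cell-type calls from a homology matrix
#'
#' A species-A type is flagged species-specific when its best co-clustering
#' proportion against every species-B type stays below `tau_specific`.
#'
#' @param hm a `hipp_homology` (or a bare proportion matrix).
#' @param tau_specific call threshold (default 0.1).
#' @return character vector of flagged species-A types.
#' @export
call_species_specific <- function(hm, tau_specific = 0.1) {
  M <- if (inherits(hm, "hipp_homology")) hm$matrix else as.matrix(hm)
  if (!length(M)) abort_validation("empty homology matrix")
  rownames(M)[apply(M, 1, max) < tau_specific]
}

#' Primate-specific cell-type calls
#'
#' A type is called primate-specific when it is flagged species-specific
#' against the mouse in both primate-vs-mouse comparisons and its
#' primate-to-primate best co-clustering proportion exceeds `tau_match`
#' (types are matched across comparisons by name, which the shared taxonomy
#' guarantees).
#'
#' @param hm_a_mouse,hm_b_mouse homology matrices of each primate vs mouse.
#' @param hm_a_b homology matrix between the two primates (A rows).
#' @param tau_specific species-specific threshold (default 0.1).
#' @param tau_match primate-primate conservation floor (default 0.3).
#' @return character vector of primate-specific type names.
#' @export
call_primate_specific <- function(hm_a_mouse, hm_b_mouse, hm_a_b,
                                  tau_specific = 0.1, tau_match = 0.3) {
  sp_a <- call_species_specific(hm_a_mouse, tau_specific)
  sp_b <- call_species_specific(hm_b_mouse, tau_specific)
  M_ab <- if (inherits(hm_a_b, "hipp_homology")) hm_a_b$matrix else as.matrix(hm_a_b)
  cand <- intersect(sp_a, sp_b)
  cand <- cand[cand %in% rownames(M_ab)]
  cand[apply(M_ab[cand, , drop = FALSE], 1, max) > tau_match]
}

#' GABAergic composition statistics per species
#'
#' The percentage of GABAergic cells among all neurons per species, and the
#' percentage of each GABAergic subclass among all GABAergic cells.
#'
#' @param cells tibble with columns `species`, `class` and `subclass`
#'   (cell-level annotation).
#' @return list with `gaba_pct` (species, n_neurons, pct_gaba) and
#'   `subclass_pct` (species, subclass, pct; sums to 100 per species).
#'   Species without neurons get NA.
#' @export
composition_stats <- function(cells) {
  need <- c("species", "class", "subclass")
  if (!all(need %in% names(cells))) abort_validation("cells needs columns: %s",
                                                     paste(need, collapse = ", "))
  neurons <- cells[cells$class %in% c("glutamatergic", "GABAergic"), ]
  gaba_pct <- cells |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_neurons = sum(.data$class %in% c("glutamatergic", "GABAergic")),
      pct_gaba = ifelse(.data$n_neurons > 0,
                        100 * sum(.data$class == "GABAergic") / .data$n_neurons,
                        NA_real_),
      .groups = "drop")
  subclass_pct <- neurons[neurons$class == "GABAergic", ] |>
    dplyr::count(.data$species, .data$subclass) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("species", "subclass", "pct")
  list(gaba_pct = gaba_pct, subclass_pct = subclass_pct)
}
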