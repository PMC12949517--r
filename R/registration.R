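#' Reference cell-type centroid profiles
#'
#' Per-type mean log-normalized expression over a stated gene set; the gene
#' set is stored so that transfer uses exactly the same genes.
#'
#' @param nm_ref reference normalized gene-by-cell matrix.
#' @param labels cell typing (named vector or `hipp_clusters`).
#' @param gene_set genes to restrict to (default: all genes).
#' @return object of class `hipp_centroids`: `profiles` (genes x types) and
#'   `n_cells` (named per-type counts).
#' @export
type_centroids <- function(nm_ref, labels, gene_set = rownames(nm_ref)) {
  missing <- setdiff(gene_set, rownames(nm_ref))
  if (length(missing)) abort_validation("genes absent from matrix: %s",
                                        paste(utils::head(missing, 5), collapse = ", "))
  g <- resolve_groups(nm_ref, labels)
  types <- sort(unique(g[!is.na(g)]))
  if (!length(types)) abort_validation("no labeled cells")
  sub <- nm_ref[gene_set, , drop = FALSE]
  profiles <- vapply(types, function(t) {
    Matrix::rowMeans(sub[, g == t & !is.na(g), drop = FALSE])
  }, numeric(length(gene_set)))
  structure(list(profiles = profiles,
                 n_cells = stats::setNames(as.integer(table(g)[types]), types),
                 gene_set = gene_set),
            class = "hipp_centroids")
}

#' Transfer reference cell-type labels onto spatial cells
#'
#' Each spatial cell is registered to the reference cell type with the
#' highest Pearson correlation between its log-normalized profile and the
#' type centroids over the centroid gene set (intersected with the spatial
#' genes). Ties break toward the type with more reference cells; cells whose
#' best correlation is below `c_min`, or whose profile has zero variance
#' over the shared genes, are left "unassigned" with a reason flag.
#'
#' @param nm_spatial spatial normalized gene-by-cell matrix.
#' @param centroids a [type_centroids()] object.
#' @param c_min minimum correlation for assignment (default 0.1).
#' @return tibble (cell_id, cell_type, best_cor, runner_up_cor, margin,
#'   reason).
#' @export
transfer_labels <- function(nm_spatial, centroids, c_min = 0.1) {
  shared <- intersect(centroids$gene_set, rownames(nm_spatial))
  if (!length(shared)) abort_validation("no shared genes between centroids and spatial matrix")
  cent <- centroids$profiles[match(shared, centroids$gene_set), , drop = FALSE]
  x <- as.matrix(nm_spatial[shared, , drop = FALSE])
  sd_cell <- apply(x, 2, stats::sd)
  zc <- scale(cent)                                    # genes x types, standardized
  zx <- scale(x)
  zx[, sd_cell == 0] <- 0
  cors <- crossprod(zx, zc) / (length(shared) - 1)     # cells x types
  n_ref <- centroids$n_cells[colnames(cent)]
  pick <- apply(cors, 1, function(r) {
    best <- max(r)
    cand <- which(r >= best - 1e-12)
    if (length(cand) > 1) cand <- cand[which.max(n_ref[cand])]
    cand[1]
  })
  best <- cors[cbind(seq_len(nrow(cors)), pick)]
  runner <- vapply(seq_len(nrow(cors)), function(i) {
    r <- cors[i, -pick[i]]
    if (length(r)) max(r) else -Inf
  }, numeric(1))
  assigned <- sd_cell > 0 & best >= c_min
  reason <- rep(NA_character_, ncol(x))
  reason[sd_cell == 0] <- "zero_variance"
  reason[sd_cell > 0 & best < c_min] <- "low_correlation"
  tibble::tibble(cell_id = colnames(nm_spatial),
                 cell_type = unname(ifelse(assigned, colnames(cent)[pick], "unassigned")),
                 best_cor = unname(ifelse(sd_cell > 0, best, NA_real_)),
                 runner_up_cor = unname(ifelse(sd_cell > 0, runner, NA_real_)),
                 margin = unname(ifelse(sd_cell > 0, best - runner, NA_real_)),
                 reason = unname(reason))
}

#' Neighbour-voting replicability AUROC between two typed datasets
#'
#' A re-implementation of the neighbour-voting idea behind cross-dataset
#' cell-type replicability scores: cells of both datasets are placed in a
#' common space of shared highly variable genes; for each cell of dataset B,
#' its `k` nearest neighbours among dataset-A cells are found by Spearman
#' correlation of expression profiles; for every shared type, B cells are
#' scored by the fraction of their A-neighbours carrying that type and the
#' score is summarised as the AUROC against the true B labels. The roles of
#' A and B are then swapped and the two AUROCs averaged. Types absent from
#' either dataset get NA.
#'
#' @param nm_a,nm_b normalized matrices.
#' @param labels_a,labels_b cell typings.
#' @param k neighbours (default 15).
#' @param n_hvgs shared highly-variable-gene depth (default 2000).
#' @return tibble (cell_type, auroc_ab, auroc_ba, auroc).
#' @export
neighbor_voting_auroc <- function(nm_a, labels_a, nm_b, labels_b, k = 15,
                                  n_hvgs = 2000) {
  ga <- resolve_groups(nm_a, labels_a)
  gb <- resolve_groups(nm_b, labels_b)
  shared_genes <- intersect(rownames(nm_a), rownames(nm_b))
  if (!length(shared_genes)) abort_validation("no shared genes")
  comb <- cbind(nm_a[shared_genes, , drop = FALSE], nm_b[shared_genes, , drop = FALSE])
  hvgs <- select_hvgs(comb, min(n_hvgs, length(shared_genes)))
  rank_std <- function(m) {
    x <- apply(as.matrix(m), 2, rank)
    z <- scale(x)
    z[, apply(x, 2, stats::sd) == 0] <- 0
    z
  }
  za <- rank_std(nm_a[hvgs, , drop = FALSE])
  zb <- rank_std(nm_b[hvgs, , drop = FALSE])

  vote <- function(z_from, g_from, z_to, g_to, type) {
    cors <- crossprod(z_from, z_to)                    # from-cells x to-cells
    kk <- min(k, nrow(cors))
    scores <- apply(cors, 2, function(r) {
      nb <- order(r, decreasing = TRUE)[seq_len(kk)]
      mean(g_from[nb] == type)
    })
    auroc(scores, g_to == type)
  }
  types <- sort(union(unique(ga), unique(gb)))
  out <- purrr::map_dfr(types, function(t) {
    if (!t %in% ga || !t %in% gb) {
      return(tibble::tibble(cell_type = t, auroc_ab = NA_real_,
                            auroc_ba = NA_real_, auroc = NA_real_))
    }
    ab <- vote(za, ga, zb, gb, t)
    ba <- vote(zb, gb, za, ga, t)
    tibble::tibble(cell_type = t, auroc_ab = ab, auroc_ba = ba,
                   auroc = mean(c(ab, ba)))
  })
  out
}
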