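# resolve a grouping argument (hipp_clusters, named vector, or factor over
# the matrix columns) to a named character vector cell -> group
resolve_groups <- function(nm, groups) {
  if (inherits(groups, "hipp_clusters")) groups <- groups$labels
  if (is.null(names(groups))) {
    if (length(groups) != ncol(nm)) abort_validation("unnamed groups must cover all cells")
    names(groups) <- colnames(nm)
  }
  g <- as.character(groups)[match(colnames(nm), names(groups))]
  stats::setNames(g, colnames(nm))
}

#' Differential expression between two cell groups
#'
#' Per gene passing the expression-fraction filter in at least one group:
#' a two-sided Wilcoxon rank-sum test on log-normalized values (exact when
#' both groups have <= 25 cells and no ties, tie-corrected normal
#' approximation otherwise), a log2 fold change of the (mean CP10K + 1)
#' ratio, and Benjamini-Hochberg correction across the tested genes. A gene
#' is flagged as a DEG when `q < alpha_q` and `|log2FC| >= min_abs_log2fc`.
#' A cell "expresses" a gene when its raw count is >= 1 (equivalently its
#' log-normalized value is > 0).
#'
#' @param nm normalized gene-by-cell matrix.
#' @param groups cell grouping: a `hipp_clusters`, or a (named) vector over
#'   cells.
#' @param group_a,group_b group labels; `group_b = NULL` contrasts
#'   `group_a` against all remaining cells.
#' @param min_frac minimum expressing fraction in at least one group (0.10).
#' @param min_abs_log2fc DEG effect-size floor (0.25).
#' @param alpha_q DEG q-value threshold (0.05).
#' @return tibble ordered by ascending q then descending |log2FC| with
#'   columns gene, group_a, group_b, log2_fold_change, p_value, q_value,
#'   frac_expr_a, frac_expr_b, direction ("up" = higher in `group_a`),
#'   is_deg.
#' @export
find_markers <- function(nm, groups, group_a, group_b = NULL, min_frac = 0.10,
                         min_abs_log2fc = 0.25, alpha_q = 0.05) {
  g <- resolve_groups(nm, groups)
  ia <- which(g == as.character(group_a))
  ib <- if (is.null(group_b)) which(g != as.character(group_a) & !is.na(g)) else
    which(g == as.character(group_b))
  lab_b <- if (is.null(group_b)) "rest" else as.character(group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    abort_validation("both groups need >= 2 cells (got %d and %d)", length(ia), length(ib))
  }
  fa <- Matrix::rowMeans(nm[, ia, drop = FALSE] > 0)
  fb <- Matrix::rowMeans(nm[, ib, drop = FALSE] > 0)
  keep <- which(fa >= min_frac | fb >= min_frac)
  if (!length(keep)) {
    return(tibble::tibble(gene = character(), group_a = character(),
                          group_b = character(), log2_fold_change = numeric(),
                          p_value = numeric(), q_value = numeric(),
                          frac_expr_a = numeric(), frac_expr_b = numeric(),
                          direction = character(), is_deg = logical()))
  }
  xa <- as.matrix(nm[keep, ia, drop = FALSE])
  xb <- as.matrix(nm[keep, ib, drop = FALSE])
  exact <- length(ia) <= 25 && length(ib) <= 25
  p <- vapply(seq_along(keep), function(i) {
    suppressWarnings(stats::wilcox.test(xa[i, ], xb[i, ], exact = exact)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  mean_a <- rowMeans(expm1(xa))
  mean_b <- rowMeans(expm1(xb))
  l2fc <- log2((mean_a + 1) / (mean_b + 1))
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(gene = rownames(nm)[keep],
                        group_a = as.character(group_a), group_b = lab_b,
                        log2_fold_change = unname(l2fc), p_value = p, q_value = q,
                        frac_expr_a = unname(fa[keep]), frac_expr_b = unname(fb[keep]),
                        direction = unname(ifelse(l2fc >= 0, "up", "down")),
                        is_deg = q < alpha_q & abs(l2fc) >= min_abs_log2fc)
  dplyr::arrange(out, .data$q_value, dplyr::desc(abs(.data$log2_fold_change)))
}

#' Top marker rows of a DEG table
#'
#' @param deg a [find_markers()] table.
#' @param n number of rows (default 10).
#' @param flagged_only keep only flagged DEGs before truncation.
#' @return the first `n` rows ordered by ascending q then descending |log2FC|.
#' @export
top_markers <- function(deg, n = 10, flagged_only = FALSE) {
  if (flagged_only) deg <- deg[deg$is_deg, , drop = FALSE]
  utils::head(dplyr::arrange(deg, .data$q_value,
                             dplyr::desc(abs(.data$log2_fold_change))), n)
}

#' Gene-set module score with expression-matched controls
#'
#' Genes are binned by mean expression across cells into `n_bins`
#' equal-occupancy bins; for every set gene, `n_ctrl` control genes are
#' drawn (seeded; without replacement where the bin allows) from the same
#' bin. The per-cell score is the mean log-normalized expression over the
#' set genes minus the mean over the pooled control genes.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param gene_set character vector of genes (subset of rownames).
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl controls per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @return tibble (cell_id, score) with the gene set and control parameters
#'   as attributes.
#' @export
module_score <- function(nm, gene_set, n_bins = 25, n_ctrl = 100, seed = 1L) {
  if (!length(gene_set)) abort_validation("gene_set is empty")
  missing <- setdiff(gene_set, rownames(nm))
  if (length(missing)) abort_validation("genes not in matrix: %s", paste(missing, collapse = ", "))
  if (n_bins < 2) abort_validation("n_bins must be >= 2")
  means <- Matrix::rowMeans(nm)
  bin <- ggplot2::cut_number(rank(means, ties.method = "first"), n = min(n_bins, nrow(nm)),
                             labels = FALSE)
  ctrl <- with_seed(seed, unlist(lapply(gene_set, function(g) {
    pool <- rownames(nm)[bin == bin[match(g, rownames(nm))]]
    if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
  })))
  set_mean <- Matrix::colMeans(nm[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(nm[ctrl, , drop = FALSE])
  out <- tibble::tibble(cell_id = colnames(nm), score = as.numeric(set_mean - ctrl_mean))
  attr(out, "gene_set") <- gene_set
  attr(out, "control") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' Fraction of cells (co-)expressing a gene combination
#'
#' A cell expresses a gene iff its raw count is >= 1; the combo fraction is
#' the share of cells in each group expressing all listed genes.
#'
#' @param m count or normalized gene-by-cell matrix (both encode count >= 1
#'   as value > 0).
#' @param groups cell grouping (see [find_markers()]).
#' @param gene_combo character vector of genes; all must be expressed.
#' @return tibble (group, n_cells, fraction).
#' @export
expression_fractions <- function(m, groups, gene_combo) {
  missing <- setdiff(gene_combo, rownames(m))
  if (length(missing)) abort_validation("genes not in matrix: %s", paste(missing, collapse = ", "))
  g <- resolve_groups(m, groups)
  expressed <- Matrix::colSums(m[gene_combo, , drop = FALSE] > 0) == length(gene_combo)
  out <- tibble::as_tibble(stats::aggregate(expressed, list(group = g), function(z) mean(z)))
  names(out)[2] <- "fraction"
  n <- table(g)
  out$n_cells <- as.integer(n[out$group])
  if (any(out$n_cells == 0)) abort_validation("empty group")
  out[, c("group", "n_cells", "fraction")]
}

#' Shared and specific marker counts across species
#'
#' Truncates each species' ordered marker list to `top_n` and counts every
#' exclusive region of the Venn partition (species-specific, each pairwise
#' overlap, shared by all).
#'
#' @param markers_by_species named list of ordered, deduplicated gene lists.
#' @param top_n truncation depth (default 200).
#' @return tibble (region, n_species, count); `region` is the
#'   `&`-joined species subset.
#' @export
marker_overlap <- function(markers_by_species, top_n = 200) {
  if (top_n <= 0) abort_validation("top_n must be > 0")
  if (any(vapply(markers_by_species, anyDuplicated, integer(1)) > 0)) {
    abort_validation("marker lists must be deduplicated")
  }
  lists <- lapply(markers_by_species, utils::head, top_n)
  genes <- unique(unlist(lists))
  memb <- vapply(lists, function(l) genes %in% l, logical(length(genes)))
  if (length(genes) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(lists)))
  key <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  all_regions <- unlist(lapply(seq_along(lists), function(k) {
    utils::combn(names(lists), k, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = all_regions))
  tibble::tibble(region = names(counts),
                 n_species = lengths(strsplit(names(counts), "&", fixed = TRUE)),
                 count = as.integer(counts))
}

#' Pseudobulk transcriptomic similarity between groups
#'
#' Per-group mean log-normalized profiles, restricted to the top
#' `n_var_genes` genes by variance across the group means, then a Pearson
#' correlation matrix.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param groups cell grouping with >= 2 groups.
#' @param n_var_genes variable-gene depth (default 100).
#' @return symmetric correlation matrix with group dimnames.
#' @export
pseudobulk_similarity <- function(nm, groups, n_var_genes = 100) {
  g <- resolve_groups(nm, groups)
  lv <- sort(unique(g[!is.na(g)]))
  if (length(lv) < 2) abort_validation("need >= 2 groups")
  prof <- vapply(lv, function(l) {
    idx <- which(g == l)
    if (!length(idx)) abort_validation("group '%s' has 0 cells", l)
    Matrix::rowMeans(nm[, idx, drop = FALSE])
  }, numeric(nrow(nm)))
  v <- apply(prof, 1, stats::var)
  top <- order(-v, rownames(nm), method = "radix")[seq_len(min(n_var_genes, nrow(prof)))]
  stats::cor(prof[top, , drop = FALSE])
}

#' Cross-species DEG overlap counts
#'
#' A DEG is shared between species iff it is flagged in both tables with
#' the same direction; counts are reported for every exclusive species
#' subset, split by direction.
#'
#' @param deg_tables named list (species -> [find_markers()] table) for the
#'   same contrast.
#' @return tibble (region, direction, count) over all species subsets.
#' @export
deg_overlap_across_species <- function(deg_tables) {
  ok <- vapply(deg_tables, function(d) "direction" %in% names(d), logical(1))
  if (!all(ok)) abort_validation("direction field missing in: %s",
                                 paste(names(deg_tables)[!ok], collapse = ", "))
  sets <- lapply(deg_tables, function(d) {
    d <- d[d$is_deg, , drop = FALSE]
    paste(d$gene, d$direction, sep = "\r")
  })
  keys <- unique(unlist(sets))
  all_regions <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  if (!length(keys)) {
    return(tidyr::expand_grid(region = all_regions, direction = c("up", "down")) |>
             dplyr::mutate(count = 0L))
  }
  memb <- vapply(sets, function(s) keys %in% s, logical(length(keys)))
  if (length(keys) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  direction <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, character(1), 2)
  counts <- table(factor(region, levels = all_regions), factor(direction, levels = c("up", "down")))
  out <- tibble::as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  names(out) <- c("region", "direction", "count")
  out$count <- as.integer(out$count)
  dplyr::arrange(out, .data$region, .data$direction)
}
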