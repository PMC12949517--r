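#' Permutation neighborhood enrichment within a section
#'
#' The observed statistic for a type pair (A, B) is the number of unordered
#' cell pairs within `radius_um` of each other in which one cell is of type
#' A and the other of type B (for A = B, pairs within the type). The null
#' distribution comes from permuting the labels within the section; the
#' z-score standardizes the observed count by the permutation mean and
#' (population) SD. Pairs in which either type has fewer than `min_cells`
#' cells, or whose null SD is zero, get NA. When the number of cells is
#' small enough that all label orderings can be enumerated within `n_perm`
#' (n! <= n_perm), the exhaustive permutation null is used instead of
#' sampling.
#'
#' @param coords two-column matrix/data frame of x/y positions (microns).
#' @param labels cell-type label per cell.
#' @param radius_um neighborhood radius (default 50).
#' @param n_perm label permutations (default 1000).
#' @param min_cells minimum per-type cell count (default 10).
#' @param seed integer seed.
#' @param section_id optional label stored in the result.
#' @return tibble (section, type_a, type_b, n_a, n_b, obs, null_mean,
#'   null_sd, z) over unordered type pairs (type_a <= type_b), with
#'   attributes `radius_um`, `n_perm`, `min_cells`.
#' @export
nhood_enrichment <- function(coords, labels, radius_um = 50, n_perm = 1000,
                             min_cells = 10, seed = 1L, section_id = NA_character_) {
  if (radius_um <= 0) abort_validation("radius_um must be > 0")
  coords <- as.matrix(coords[, 1:2])
  labels <- as.character(labels)
  n <- nrow(coords)
  if (length(labels) != n) abort_validation("labels must match coords rows")
  types <- sort(unique(labels))
  if (length(types) < 2) {
    warning("fewer than 2 labeled types in section; all scores NA", call. = FALSE)
  }
  K <- length(types)
  code <- match(labels, types)
  d <- as.matrix(stats::dist(coords))
  adj <- which(upper.tri(d) & d <= radius_um, arr.ind = TRUE)
  pair_counts <- function(cd) {
    a <- pmin(cd[adj[, 1]], cd[adj[, 2]])
    b <- pmax(cd[adj[, 1]], cd[adj[, 2]])
    tabulate((a - 1) * K + b, nbins = K * K)
  }
  obs <- pair_counts(code)
  exhaustive <- n <= 170 && factorial(n) <= n_perm
  perms <- if (exhaustive) {
    all_perms <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(all_perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    all_perms(seq_len(n))
  } else NULL
  n_draws <- if (exhaustive) length(perms) else n_perm
  sums <- numeric(K * K)
  sq <- numeric(K * K)
  with_seed(seed, {
    for (r in seq_len(n_draws)) {
      idx <- if (exhaustive) perms[[r]] else sample.int(n)
      pc <- pair_counts(code[idx])
      sums <- sums + pc
      sq <- sq + pc^2
    }
  })
  mu <- sums / n_draws
  sdv <- sqrt(pmax(sq / n_draws - mu^2, 0))
  grid <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  ia <- grid[, 1]; ib <- grid[, 2]
  flat <- (ia - 1) * K + ib
  n_type <- tabulate(code, nbins = K)
  ok <- n_type[ia] >= min_cells & n_type[ib] >= min_cells & sdv[flat] > 0
  z <- ifelse(ok, (obs[flat] - mu[flat]) / sdv[flat], NA_real_)
  out <- tibble::tibble(section = section_id,
                        type_a = types[ia], type_b = types[ib],
                        n_a = n_type[ia], n_b = n_type[ib],
                        obs = obs[flat], null_mean = mu[flat],
                        null_sd = sdv[flat], z = z)
  attr(out, "radius_um") <- radius_um
  attr(out, "n_perm") <- n_draws
  attr(out, "min_cells") <- min_cells
  out
}

#' Longitudinal trend of a neighborhood score
#'
#' Spearman correlation of per-section z-scores against the longitudinal
#' coordinate over non-NA sections (exact p for n <= 9 without ties),
#' with conventional significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param z_by_section tibble with columns `axis_mm` and `z` (one row per
#'   section for one type pair).
#' @param min_sections minimum non-NA sections (default 5).
#' @return one-row tibble (rho, p_value, stars, n_sections); NA-filled with
#'   reason "too_few_sections" below `min_sections`.
#' @export
axis_trend <- function(z_by_section, min_sections = 5) {
  ok <- !is.na(z_by_section$z)
  n <- sum(ok)
  if (n < min_sections) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, stars = "",
                          n_sections = n, reason = "too_few_sections"))
  }
  x <- z_by_section$axis_mm[ok]
  y <- z_by_section$z[ok]
  if (stats::sd(y) == 0) {
    return(tibble::tibble(rho = 0, p_value = 1, stars = "", n_sections = n,
                          reason = NA_character_))
  }
  exact <- n <= 9 && !anyDuplicated(y) && !anyDuplicated(x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  p <- ct$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  tibble::tibble(rho = unname(ct$estimate), p_value = p, stars = stars,
                 n_sections = n, reason = NA_character_)
}

#' Ligand-receptor interaction scores between two cell types
#'
#' For each (ligand, receptor) pair: the mean log-normalized ligand
#' expression in the sender type times the mean log-normalized receptor
#' expression in the receiver type. The score is gated to zero unless the
#' ligand is expressed (count >= 1) in at least `min_frac` of sender cells
#' and the receptor in at least `min_frac` of receiver cells. A deliberately
#' simple product-of-means statistic with fraction gating.
#'
#' @param nm_ref reference normalized matrix.
#' @param labels cell typing.
#' @param pairs tibble with columns `ligand` and `receptor`.
#' @param sender,receiver cell-type labels.
#' @param min_frac gating fraction (default 0.10).
#' @return tibble (ligand, receptor, sender, receiver, score, gated,
#'   gate_reason).
#' @export
ligand_receptor_score <- function(nm_ref, labels, pairs, sender, receiver,
                                  min_frac = 0.10) {
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    abort_validation("pairs needs columns ligand and receptor")
  }
  g <- resolve_groups(nm_ref, labels)
  si <- which(g == sender)
  ri <- which(g == receiver)
  if (!length(si)) abort_validation("unknown or empty sender type '%s'", sender)
  if (!length(ri)) abort_validation("unknown or empty receiver type '%s'", receiver)
  missing <- setdiff(unique(c(pairs$ligand, pairs$receptor)), rownames(nm_ref))
  if (length(missing)) abort_validation("genes absent: %s", paste(missing, collapse = ", "))
  mean_s <- Matrix::rowMeans(nm_ref[pairs$ligand, si, drop = FALSE])
  mean_r <- Matrix::rowMeans(nm_ref[pairs$receptor, ri, drop = FALSE])
  frac_s <- Matrix::rowMeans(nm_ref[pairs$ligand, si, drop = FALSE] > 0)
  frac_r <- Matrix::rowMeans(nm_ref[pairs$receptor, ri, drop = FALSE] > 0)
  gated <- frac_s < min_frac | frac_r < min_frac
  reason <- dplyr::case_when(
    frac_s < min_frac & frac_r < min_frac ~ "ligand_and_receptor_below_min_frac",
    frac_s < min_frac ~ "ligand_below_min_frac",
    frac_r < min_frac ~ "receptor_below_min_frac",
    TRUE ~ NA_character_)
  tibble::tibble(ligand = pairs$ligand, receptor = pairs$receptor,
                 sender = sender, receiver = receiver,
                 score = unname(ifelse(gated, 0, as.numeric(mean_s) * as.numeric(mean_r))),
                 gated = unname(gated), gate_reason = reason)
}
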