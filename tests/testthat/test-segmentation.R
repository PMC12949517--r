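test_that("spatial smoothing has its identity, fixed-point and averaging forms", {
  nm <- fx_nm_spatial()[, 1:120]
  co <- fx_spatial()$cells[1:120, c("x_um", "y_um")]
  expect_identical(spatial_smooth(nm, co, 0), nm)
  # spatially constant expression is a fixed point
  const <- toy_nm(matrix(rep(c(1, 2, 3), 5), nrow = 3),
                  cells = sprintf("c%d", 1:5))
  co5 <- data.frame(x = 1:5, y = rep(0, 5))
  expect_equal(as.matrix(spatial_smooth(const, co5, 2)), as.matrix(const))
  # 3 collinear cells, k = 1: each cell averages itself and its nearest
  vals <- matrix(c(1, 0, 0,
                   0, 1, 0), nrow = 2, byrow = TRUE)
  nm3 <- toy_nm(vals)
  co3 <- data.frame(x = c(0, 1, 10), y = 0)
  sm <- as.matrix(spatial_smooth(nm3, co3, 1))
  expect_equal(unname(sm),
               matrix(c(0.5, 0.5, 0, 0.5, 0.5, 0.5), nrow = 2, byrow = TRUE))
  expect_error(spatial_smooth(nm3, co3, 3), class = "hippatlas_validation_error")
})

test_that("noiseless banded sections segment into exactly the planted bands", {
  set.seed(21)
  n_band <- 60
  band <- rep(1:3, each = n_band)
  vals <- matrix(0.1, 30, 3 * n_band)
  for (b in 1:3) vals[(b - 1) * 10 + 1:10, band == b] <- 5
  nm <- toy_nm(vals)
  co <- data.frame(x = runif(3 * n_band, 0, 300),
                   y = runif(3 * n_band) * 80 + (band - 1) * 120)
  m <- segment_section(nm, co, k_spatial = 5, seed = 7L)
  expect_equal(ncol(m$centroids), 3)
  expect_equal(ari(m$labels, band), 1)
  m2 <- segment_section(nm, co, k_spatial = 5, seed = 7L)
  expect_identical(m$labels, m2$labels)
})

test_that("segmentation is invariant to rigid motions of the section", {
  nm <- fx_nm_spatial()
  idx <- fx_spatial()$cells$section_id == "macaque_S01"
  co <- as.matrix(fx_spatial()$cells[idx, c("x_um", "y_um")])
  m1 <- segment_section(nm[, idx], co, seed = 5L)
  th <- pi / 5
  rot <- co %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2) + 500
  m2 <- segment_section(nm[, idx], rot, seed = 5L)
  expect_identical(m1$labels, m2$labels)
})

test_that("laminar pre/para-subicular strata are resolved and depth-ordered", {
  sp <- fx_spatial()
  nm <- fx_nm_spatial()
  truth <- sp$truth$cells
  idx <- sp$cells$section_id == "macaque_S06"  # posterior: all three strata populated
  m <- segment_section(nm[, idx], sp$cells[idx, c("x_um", "y_um")], seed = 5L)
  sub <- truth$subregion[idx]
  depth <- truth$depth_frac[idx]
  per_cl <- tibble::tibble(cl = m$labels, sub = sub, depth = depth) |>
    dplyr::group_by(cl) |>
    dplyr::summarise(frac_psub = mean(startsWith(sub, "pSUB")),
                     stratum = names(sort(table(sub), decreasing = TRUE))[1],
                     mean_depth = mean(depth), .groups = "drop") |>
    dplyr::filter(frac_psub > 0.5)
  expect_gte(nrow(per_cl), 3)
  expect_gte(length(unique(per_cl$stratum)), 3)
  ord <- per_cl[order(per_cl$mean_depth), ]
  expect_identical(ord$stratum[1], "pSUB-sup")
  expect_identical(ord$stratum[nrow(ord)], "pSUB-deep")
})

test_that("jaccard index follows set arithmetic", {
  expect_equal(jaccard_index(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(jaccard_index(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_true(is.na(jaccard_index(character(0), character(0))))
})

test_that("cross-section matching pairs clusters and reports the unmatched", {
  sp <- fx_spatial()
  nm <- fx_nm_spatial()
  secs <- c("macaque_S01", "macaque_S02")
  maps <- lapply(secs, function(sec) {
    idx <- sp$cells$section_id == sec
    segment_section(nm[, idx], sp$cells[idx, c("x_um", "y_um")],
                    seed = 5L, section_id = sec)
  })
  mm <- match_subregions_across_sections(maps)
  corr <- mm$correspondence
  ref_rows <- corr[corr$section == mm$reference_section, ]
  expect_equal(ref_rows$jaccard, rep(1, nrow(ref_rows)))
  other <- corr[corr$section != mm$reference_section, ]
  matched <- other[!is.na(other$ref_cluster), ]
  expect_false(anyDuplicated(matched$ref_cluster) > 0)  # one-to-one
  n_min <- min(ncol(maps[[1]]$centroids), ncol(maps[[2]]$centroids))
  expect_equal(nrow(matched), n_min)  # surplus clusters reported unmatched
  expect_error(match_subregions_across_sections(maps[1]),
               class = "hippatlas_validation_error")
})

test_that("matched subregions are consistent across the section series", {
  sp <- fx_spatial()
  nm <- fx_nm_spatial()
  secs <- unique(sp$cells$section_id)
  maps <- lapply(secs, function(sec) {
    idx <- sp$cells$section_id == sec
    segment_section(nm[, idx], sp$cells[idx, c("x_um", "y_um")],
                    seed = 5L, section_id = sec)
  })
  mm <- match_subregions_across_sections(maps)
  expect_gte(mean(mm$section_consistency$mean_jaccard), 0.6)
  .fx_env$seg_maps <- maps  # reused by the annotation test below
})

test_that("marker panels annotate subregion clusters with a margin rule", {
  sp <- fx_spatial()
  nm <- fx_nm_spatial()
  tax <- fx_tax()
  maps <- .fx_env$seg_maps
  idx <- sp$cells$section_id == "macaque_S01"
  ann <- annotate_subregions(maps[[1]], nm[, idx], default_marker_panel(tax), seed = 2L)
  truth <- sp$truth$cells$subregion[idx]
  # majority truth band per cluster should agree with the annotation for
  # most assigned clusters
  lab <- ann$annotation[as.character(ann$labels)]
  sub2band <- function(x) ifelse(x %in% c("pSUB-deep", "pSUB-int", "pSUB-sup"), x, x)
  agree <- mean(lab[lab != "unassigned"] == sub2band(truth)[lab != "unassigned"])
  expect_gt(agree, 0.7)
  # tie rule: two identical panels cannot exceed the margin
  panel <- default_marker_panel(tax)["DG-gr"]
  two <- c(panel, stats::setNames(panel, "copy"))
  ann2 <- annotate_subregions(maps[[1]], nm[, idx], two, seed = 2L)
  expect_true(all(ann2$annotation == "unassigned"))
  expect_error(annotate_subregions(maps[[1]], nm[, idx], list()),
               class = "hippatlas_validation_error")
})
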