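mk_cells <- function(n_per_section, types_by_section, spacing = 0.5) {
  sec <- rep(seq_along(n_per_section), n_per_section)
  tibble::tibble(cell_id = sprintf("c%04d", seq_len(sum(n_per_section))),
                 species = "macaque", modality = "spatial",
                 section_id = sprintf("S%02d", sec),
                 x_um = 0, y_um = 0,
                 axis_mm = (sec - 1) * spacing,
                 subregion = NA_character_,
                 cell_type = unlist(types_by_section),
                 depth_frac = 0.5)
}

test_that("positional profiles normalize per-section densities", {
  cells <- mk_cells(c(100, 100, 100, 100),
                    lapply(c(10, 20, 30, 40), function(k)
                      rep(c("T", "other"), c(k, 100 - k))))
  p <- positional_profile(cells, "T", "axis")
  expect_equal(p$relative, c(10, 20, 30, 40) / 100)
  expect_equal(sum(p$relative), 1)
  # entity = all cells: flat 1/S
  pall <- positional_profile(dplyr::mutate(cells, cell_type = "T"), "T", "axis")
  expect_equal(pall$relative, rep(1 / 4, 4))
  # point mass
  one <- mk_cells(c(60, 60, 60), list(rep(c("T", "o"), c(10, 50)),
                                      rep("o", 60), rep("o", 60)))
  p1 <- positional_profile(one, "T", "axis")
  expect_equal(p1$relative, c(1, 0, 0))
  # sections under the inclusion floor are excluded and listed
  small <- mk_cells(c(100, 100, 30), lapply(1:3, function(i) rep("T", c(100, 100, 30)[i])))
  ps <- positional_profile(small, "T", "axis", m_min = 50)
  expect_equal(nrow(ps), 2)
  expect_identical(attr(ps, "excluded_sections"), "S03")
  # absent entity flagged
  pa <- positional_profile(cells, "missing", "axis")
  expect_true(attr(pa, "absent"))
})

test_that("heterogeneity is the log sample SD with a floor", {
  uni <- tibble::tibble(relative = rep(0.25, 4))
  expect_equal(heterogeneity(uni), log(1e-6))
  point <- tibble::tibble(relative = c(1, 0, 0, 0))
  expect_equal(heterogeneity(point), log(0.5))
  expect_error(heterogeneity(tibble::tibble(relative = c(1, 0))),
               class = "hippatlas_validation_error")
})

test_that("heterogeneity grows with the planted gradient slope", {
  tax <- fx_tax()
  het <- vapply(c(0.4, 1.0, 1.6), function(sl) {
    sp <- simulate_sections(tax, "macaque", axis_slope = sl, seed = 77L)
    cells <- sp$cells
    cells$cell_type <- sp$truth$cells$type
    heterogeneity(positional_profile(cells, "Glu SUB-1", "axis"))
  }, numeric(1))
  expect_true(all(diff(het) > 0))
})

test_that("non-neuronal uniform types are less heterogeneous than gradient types", {
  cells <- fx_spatial_cells()
  h <- function(t) heterogeneity(positional_profile(cells, t, "axis"))
  grad <- c("Glu SUB-1", "Glu CA3/4-2", "Glu pSUB-int-2")
  flat <- c("Astrocyte-1", "Olig-1")
  expect_true(max(vapply(flat, h, numeric(1))) <
                min(vapply(grad, h, numeric(1))))
})

test_that("preference classification uses exact Spearman significance", {
  inc <- tibble::tibble(axis_mm = 0:4, relative = c(0.1, 0.15, 0.2, 0.25, 0.3))
  cp <- classify_preference(inc)
  expect_equal(cp$preference, "posterior")
  expect_equal(cp$rho, 1)
  expect_equal(cp$p_value, 2 / 120, tolerance = 1e-10)
  expect_equal(classify_preference(inc, reversed_axis = TRUE)$preference, "anterior")
  flat <- tibble::tibble(axis_mm = 0:4, relative = rep(0.2, 5))
  expect_equal(classify_preference(flat)$preference, "uniform")
  expect_error(classify_preference(inc[1:4, ]), class = "hippatlas_validation_error")
})

test_that("planted anterior/posterior calls agree between primates and flip in mouse", {
  tax <- fx_tax()
  calls <- lapply(c("macaque", "marmoset", "mouse"), function(spc) {
    sp <- simulate_sections(tax, spc, seed = 500L + nchar(spc))
    cells <- sp$cells
    cells$cell_type <- sp$truth$cells$type
    rv <- tax$reversed_axis[[spc]]
    vapply(c("Glu CA3/4-2", "Glu pSUB-int-4"), function(t) {
      if (!t %in% cells$cell_type) return(NA_character_)
      classify_preference(positional_profile(cells, t, "axis"),
                          reversed_axis = rv)$preference
    }, character(1))
  })
  names(calls) <- c("macaque", "marmoset", "mouse")
  # concordant type: same call in both primates and (after axis reversal) mouse
  expect_equal(calls$macaque[["Glu CA3/4-2"]], "anterior")
  expect_equal(calls$marmoset[["Glu CA3/4-2"]], "anterior")
  expect_equal(calls$mouse[["Glu CA3/4-2"]], "anterior")
  # the planted discordant subicular type flips between the primates
  expect_equal(calls$macaque[["Glu pSUB-int-4"]], "anterior")
  expect_equal(calls$marmoset[["Glu pSUB-int-4"]], "posterior")
})

test_that("subregion dominance uses a strict 0.4 threshold", {
  expect_equal(subregion_dominance(c(a = 0.45, b = 0.3, c = 0.25)), "a")
  expect_true(is.na(subregion_dominance(c(a = 0.40, b = 0.35, c = 0.25))))
  expect_true(is.na(subregion_dominance(c(a = 0.39, b = 0.35, c = 0.26))))
  expect_error(subregion_dominance(c(a = -0.1, b = 0.5)),
               class = "hippatlas_validation_error")
})

test_that("gene-family scores are z-scored section fractions", {
  cells <- fx_spatial_cells()
  sp <- fx_spatial()
  ca1 <- cells$cell_id[cells$cell_type %in% c("Glu CA1-1", "Glu CA1-2")]
  fam <- gene_family_score(sp$expr, cells, ca1, fx_tax()$families$HCN_like)
  expect_equal(mean(fam$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(fam$z), 1, tolerance = 1e-10)
  # constant fractions give all-zero z
  counts <- expression_matrix(matrix(c(1, 1, 1, 1, 1, 1), nrow = 2,
                                     dimnames = list(c("f1", "o1"), sprintf("c%d", 1:3))))
  cc <- tibble::tibble(cell_id = sprintf("c%d", 1:3), species = "x",
                       modality = "spatial", section_id = c("a", "b", "c"),
                       x_um = 0, y_um = 0, axis_mm = c(0, 1, 2),
                       subregion = NA, cell_type = "T", depth_frac = 0.5)
  f2 <- gene_family_score(counts, cc, cc$cell_id, "f1")
  expect_equal(f2$z, rep(0, 3))
})

test_that("the planted HCN-like family shows its U-shaped profile", {
  cells <- fx_spatial_cells()
  sp <- fx_spatial()
  ca1 <- cells$cell_id[cells$cell_type %in% c("Glu CA1-1", "Glu CA1-2")]
  fam <- gene_family_score(sp$expr, cells, ca1, fx_tax()$families$HCN_like)
  ends <- fam$z[c(1, nrow(fam))]
  mid <- fam$z[4:5]
  expect_true(min(ends) > max(mid))
  expect_true(ushape_test(fam)$ushape)
})

test_that("the U-shape test separates quadratic from linear profiles", {
  a <- seq(0, 1, length.out = 11)
  quad <- tibble::tibble(axis_mm = a, relative = (a - 0.5)^2)
  ut <- ushape_test(quad, value = "relative")
  expect_true(ut$ushape)
  expect_equal(ut$vertex, 0.5, tolerance = 1e-8)
  expect_gt(ut$curvature, 0)
  lin <- tibble::tibble(axis_mm = a, relative = 2 * a + 1)
  expect_false(ushape_test(lin, value = "relative")$ushape)
  expect_error(ushape_test(tibble::tibble(axis_mm = rep(1, 6), relative = 1:6),
                           value = "relative"),
               class = "hippatlas_validation_error")
  expect_error(ushape_test(quad[1:5, ], value = "relative"),
               class = "hippatlas_validation_error")
})

test_that("channel-panel clustering recovers the two planted CA1 programs", {
  tax <- fx_tax()
  # near-noiseless: at exactly zero noise all cells of a program collapse
  # onto one point and nearest-neighbour ties are arbitrary
  quiet <- noise_params(dispersion = 0.05, library_sdlog = 0.1)
  sp <- simulate_sections(tax, "macaque",
                          default_section_specs("macaque", 6, 400),
                          capture_rate = 1, noise = quiet, seed = 71L)
  cells <- sp$cells
  cells$cell_type <- sp$truth$cells$type
  nm <- normalize_log_cp10k(sp$expr)
  ca1 <- cells$cell_id[cells$cell_type %in% c("Glu CA1-1", "Glu CA1-2")]
  cp <- channel_panel_clusters(nm, cells, ca1, tax$channel_panel, seed = 5L)
  expect_equal(length(unique(cp$clusters$labels)), 2)
  expect_equal(ari(cp$clusters$labels[ca1],
                   cells$cell_type[match(ca1, cells$cell_id)]), 1)
  # planted programs segregate along the axis
  mean_axis <- cp$profiles |> dplyr::distinct(.data$cluster, .data$mean_axis_mm)
  expect_equal(nrow(mean_axis), 2)
  axis_by_cl <- split(cells$axis_mm[match(ca1, cells$cell_id)], cp$clusters$labels[ca1])
  expect_lt(stats::wilcox.test(axis_by_cl[[1]], axis_by_cl[[2]])$p.value, 0.05)
  # degenerate panel
  const <- toy_nm(matrix(1, 2, 10), genes = c("p1", "p2"))
  expect_error(channel_panel_clusters(const, cc <- NULL, colnames(const), c("p1", "p2")),
               class = "hippatlas_degenerate_error")
})
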