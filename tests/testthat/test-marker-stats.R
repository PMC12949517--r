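test_that("rank-sum test reproduces the exhaustive-enumeration p-value", {
  # {1,2,3} vs {4,5,6}: U = 0, two-sided exact p = 2/20 = 0.1
  nm <- toy_nm(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1), genes = "g1")
  groups <- stats::setNames(rep(c("A", "B"), each = 3), colnames(nm))
  deg <- find_markers(nm, groups, "A", "B", min_frac = 0)
  expect_equal(deg$p_value, 0.1)
  expect_equal(deg$q_value, 0.1)
  expect_equal(deg$direction, "down")
})

test_that("identical distributions give zero fold change and no flag", {
  vals <- matrix(rep(c(0, 1, 2, 0), 10), nrow = 5, byrow = TRUE)
  nm <- toy_nm(cbind(vals, vals))
  groups <- stats::setNames(rep(c("A", "B"), each = 8), colnames(nm))
  deg <- find_markers(nm, groups, "A", "B", min_frac = 0)
  expect_true(all(deg$log2_fold_change == 0))
  expect_false(any(deg$is_deg))
})

test_that("marker tables are ordered and symmetric under group swap", {
  nm <- fx_nm_ref()
  truth <- fx_ref()$truth$cells
  groups <- stats::setNames(truth$subclass, truth$cell_id)
  ab <- find_markers(nm, groups, "DG", "CA1")
  ba <- find_markers(nm, groups, "CA1", "DG")
  m <- match(ab$gene, ba$gene)
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change[m], tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value[m], tolerance = 1e-12)
  top <- top_markers(ab, 10)
  expect_equal(nrow(top), 10)
  expect_true(!is.unsorted(top$q_value))
  # BH monotonicity: q non-decreasing in p rank and q >= p
  o <- order(ab$p_value)
  expect_true(!is.unsorted(ab$q_value[o]))
  expect_true(all(ab$q_value >= ab$p_value - 1e-15))
  expect_error(find_markers(nm, groups, "DG", "no-such-group"),
               class = "hippatlas_validation_error")
})

test_that("planted subclass markers dominate the DEG ranking", {
  nm <- fx_nm_ref()
  tax <- fx_tax()
  truth <- fx_ref()$truth$cells
  groups <- stats::setNames(truth$subclass, truth$cell_id)
  for (sc in c("DG", "SST")) {
    deg <- find_markers(nm, groups, sc)
    mk <- names(tax$subclasses$markers[[match(sc, tax$subclasses$subclass)]])
    decile <- ceiling(nrow(deg) / 10)
    expect_gte(mean(match(mk, deg$gene) <= decile), 0.95)
  }
})

test_that("module scores match a brute-force oracle on a toy matrix", {
  vals <- matrix(c(5, 6, 7, 8, 9,
                   4, 5, 6, 7, 8,
                   3, 3, 3, 3, 3,
                   0, 1, 0, 1, 0,
                   1, 0, 1, 0, 1,
                   0, 0, 1, 1, 0), nrow = 6, byrow = TRUE)
  nm <- toy_nm(vals)
  set <- c("g01", "g02")
  # n_ctrl > bin size: the control pool is each set gene's whole bin,
  # so the expected score has a closed form
  ms <- module_score(nm, set, n_bins = 2, n_ctrl = 100, seed = 1L)
  means <- rowMeans(vals)
  bin <- rank(means, ties.method = "first") > 3  # upper-occupancy bin
  pool <- rownames(nm)[bin]                      # both set genes sit there
  expected <- colMeans(vals[1:2, ]) - colMeans(vals[rownames(nm) %in% rep(pool, 2), ])
  expect_equal(ms$score, unname(expected))
  # determinism and the all-identical null
  expect_identical(ms$score, module_score(nm, set, n_bins = 2, seed = 1L)$score)
  flat <- toy_nm(matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6))
  expect_equal(module_score(flat, c("g01", "g05"), seed = 2L)$score, rep(0, 4))
  expect_error(module_score(nm, character(0)), class = "hippatlas_validation_error")
})

test_that("expression fractions count co-expressing cells", {
  counts <- expression_matrix(matrix(c(1, 0,  2, 1,  0, 1,  3, 2), nrow = 2,
                                     dimnames = list(c("gx", "gy"),
                                                     sprintf("c%d", 1:4))))
  g <- stats::setNames(rep("grp", 4), colnames(counts))
  expect_equal(expression_fractions(counts, g, "gx")$fraction, 3 / 4)
  expect_equal(expression_fractions(counts, g, c("gx", "gy"))$fraction, 2 / 4)
  # disjoint single-gene expression
  dis <- expression_matrix(matrix(c(1, 0, 0, 1), nrow = 2,
                                  dimnames = list(c("gx", "gy"), c("c1", "c2"))))
  expect_equal(expression_fractions(dis, c(c1 = "g", c2 = "g"), c("gx", "gy"))$fraction, 0)
})

test_that("marker overlap partitions the Venn regions exactly", {
  ov <- marker_overlap(list(A = c("x", "y"), B = c("y", "z"), C = "y"), top_n = 10)
  get <- function(r) ov$count[ov$region == r]
  expect_equal(get("A&B&C"), 1)
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("C"), 0)
  expect_equal(get("A&B"), 0)
  ident <- marker_overlap(list(A = letters[1:5], B = letters[1:5]), top_n = 3)
  expect_equal(ident$count[ident$region == "A&B"], 3)
  expect_equal(sum(ident$count), 3)
  expect_error(marker_overlap(list(A = c("a", "a")), top_n = 2),
               class = "hippatlas_validation_error")
})

test_that("pseudobulk similarity is higher for sibling programs", {
  nm <- fx_nm_ref()
  truth <- fx_ref()$truth$cells
  keep <- truth$type %in% c("Glu CA3/4-1", "Glu CA3/4-2", "Glu DG-1")
  cc <- pseudobulk_similarity(nm[, keep],
                              stats::setNames(truth$type[keep], truth$cell_id[keep]))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_gt(cc["Glu CA3/4-1", "Glu CA3/4-2"], cc["Glu CA3/4-1", "Glu DG-1"])
})

test_that("cross-species DEG overlap is direction-aware", {
  t1 <- tibble::tibble(gene = c("a", "b", "c"), direction = c("up", "up", "down"),
                       is_deg = TRUE)
  # duplicated table: everything shared by both
  dup <- deg_overlap_across_species(list(X = t1, Y = t1))
  expect_equal(sum(dup$count[dup$region == "X&Y"]), 3)
  expect_equal(sum(dup$count[dup$region %in% c("X", "Y")]), 0)
  # opposite direction makes a gene species-specific on both sides
  t2 <- t1
  t2$direction <- c("down", "up", "down")
  opp <- deg_overlap_across_species(list(X = t1, Y = t2))
  expect_equal(sum(opp$count[opp$region == "X&Y"]), 2)
  expect_equal(sum(opp$count[opp$region == "X"]), 1)
  expect_equal(sum(opp$count[opp$region == "Y"]), 1)
  # three enumerated tables
  t3 <- tibble::tibble(gene = c("a", "d"), direction = c("up", "up"), is_deg = TRUE)
  tri <- deg_overlap_across_species(list(X = t1, Y = t1, Z = t3))
  expect_equal(sum(tri$count[tri$region == "X&Y&Z"]), 1)   # a/up
  expect_equal(sum(tri$count[tri$region == "X&Y"]), 2)     # b/up, c/down
  expect_equal(sum(tri$count[tri$region == "Z"]), 1)       # d/up
  expect_error(deg_overlap_across_species(list(X = t1[, c("gene", "is_deg")])),
               class = "hippatlas_validation_error")
})
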