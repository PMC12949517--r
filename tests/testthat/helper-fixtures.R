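# Shared fixtures, built lazily once per test run.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- build()
  .fx_env[[name]]
}

fx_tax <- function() fx("tax", function() default_taxonomy())

# small single-species reference (800 cells) and its normalized matrix
fx_ref <- function() fx("ref", function() {
  simulate_reference(fx_tax(), "macaque", 800, seed = 301L)
})
fx_nm_ref <- function() fx("nm_ref", function() normalize_log_cp10k(fx_ref()$expr))

# default-scale spatial dataset for one species (8 sections x 600 cells)
fx_spatial <- function() fx("spatial", function() {
  simulate_sections(fx_tax(), "macaque", seed = 302L)
})
fx_nm_spatial <- function() fx("nm_spatial", function() normalize_log_cp10k(fx_spatial()$expr))

# spatial cell table with ground-truth typing filled in
fx_spatial_cells <- function() fx("spatial_cells", function() {
  sp <- fx_spatial()
  cells <- sp$cells
  cells$cell_type <- sp$truth$cells$type
  cells$subregion <- sp$truth$cells$subregion
  cells
})

# full-scale three-species reference simulations shared by the acceptance
# tests (3,000 cells per species, default taxonomy and noise)
fx_acc_refs <- function() fx("acc_refs", function() {
  species <- c("macaque", "marmoset", "mouse")
  lapply(stats::setNames(species, species), function(sp) {
    simulate_reference(fx_tax(), sp, 3000,
                       seed = hippatlas:::derive_seed(7L, paste0("acc:", sp)))
  })
})

# tiny dense normalized-like matrix helper
toy_nm <- function(values, genes = NULL, cells = NULL) {
  m <- Matrix::Matrix(values, sparse = TRUE)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  methods::as(m, "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
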