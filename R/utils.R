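# Internal helpers: error classes, seeded evaluation, sparse row moments.

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hippatlas_validation_error")
}

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hippatlas_format_error")
}

abort_integrity <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hippatlas_integrity_error")
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hippatlas_degenerate_error")
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derived from a global seed and a label;
# kept strictly below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Row variances of a (possibly sparse) genes x cells matrix, ddof = 1.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  mu <- Matrix::rowMeans(m)
  ssq <- Matrix::rowSums(m * m)
  v <- (ssq - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  stats::setNames(as.numeric(v), rownames(m))
}

# Rank-sum AUROC of numeric scores against a logical positive-class vector.
auroc <- function(scores, positive) {
  n1 <- sum(positive)
  n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# k nearest neighbours (excluding self) in a cells x dims coordinate matrix,
# computed in row blocks to bound memory. Returns an n x k index matrix.
knn_indices <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  if (k >= n) abort_validation("k_neighbors (%d) must be < number of cells (%d)", k, n)
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
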