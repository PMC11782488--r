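# Internal helpers: input validation and seeded evaluation.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the current RNG stream is used as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Canonical count matrix: base integer-ish matrix, genes in rows, cells in
# columns, both dimnames set. Sparse Matrix input is densified (datasets at
# the scale this package targets are small enough).
validate_counts <- function(counts, cells = NULL, arg = "counts") {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x cells).", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must have gene rownames and cell colnames.", arg))
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort(sprintf("`%s` must contain non-negative integer UMI counts.", arg))
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicated gene ids in count matrix.")
  if (anyDuplicated(colnames(counts))) abort("Duplicated cell ids in count matrix.")
  if (!is.null(cells)) {
    if (!identical(colnames(counts), cells$cell_id)) {
      abort("Count matrix columns do not match `cells$cell_id` (same ids, same order, required).")
    }
  }
  counts
}

# Cell profiles: tibble with cell_id, total_umis and (usually) radial_position.
validate_cells <- function(cells, need_position = TRUE) {
  if (!is.data.frame(cells)) abort("`cells` must be a data frame.")
  cells <- tibble::as_tibble(cells)
  req <- c("cell_id", "total_umis")
  miss <- setdiff(req, names(cells))
  if (length(miss)) abort(paste0("`cells` is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(cells$cell_id)) abort("`cells$cell_id` must be unique.")
  if (any(cells$total_umis < 1)) abort("`cells$total_umis` must be >= 1.")
  if (need_position) {
    if (!"radial_position" %in% names(cells)) {
      abort("`cells` needs a `radial_position` column; use add_radial_position() first.")
    }
    r <- cells$radial_position
    if (anyNA(r) || any(r < 0 | r > 1)) abort("`radial_position` must lie in [0, 1].")
  }
  cells
}

check_prob <- function(p, arg = "p") {
  if (anyNA(p) || any(p < 0 | p > 1)) abort(sprintf("`%s` must lie in [0, 1].", arg))
  invisible(p)
}

loguniform <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
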