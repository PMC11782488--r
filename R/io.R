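#' Map dye intensities to radial positions on the core-periphery axis
#'
#' Cells in a spheroid incubated with a partially diffusing dye (Calcein-AM)
#' take up an amount of dye that decreases with their depth from the surface.
#' The radial position of each cell is estimated by min-max scaling the log
#' dye intensity: `r = (log I - lo) / (hi - lo)`, clipped to `[0, 1]`, so the
#' dimmest cell (spheroid core) maps near `r = 0` and the brightest cell
#' (periphery) near `r = 1`.
#'
#' `lo` and `hi` default to the minimum and maximum of the log intensities;
#' `clip_quantiles = c(0.01, 0.01)` instead uses the 1st and 99th percentile,
#' which is robust to isolated outlier cells, at the price of clipping the
#' extreme cells exactly to 0 or 1.
#'
#' @param intensity Vector of positive dye intensities (arbitrary
#'   fluorescence units). Names, when present, are used in error messages.
#' @param clip_quantiles Length-2 numeric in `[0, 0.5)`: the lower and upper
#'   tail probabilities defining the scaling anchors. `c(0, 0)` (default) is
#'   plain min-max scaling.
#' @return Numeric vector of radial positions in `[0, 1]`, same length and
#'   names as `intensity`.
#' @examples
#' compute_radial_position(c(exp(1), exp(2), exp(3)))
#' @export
compute_radial_position <- function(intensity, clip_quantiles = c(0, 0)) {
  if (length(clip_quantiles) != 2 || anyNA(clip_quantiles) ||
      any(clip_quantiles < 0 | clip_quantiles >= 0.5)) {
    abort("`clip_quantiles` must be two values in [0, 0.5).")
  }
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad)) {
    who <- if (!is.null(names(intensity))) names(intensity)[bad[1]] else paste("element", bad[1])
    abort(sprintf("Dye intensities must be positive and finite; offending cell: %s.", who))
  }
  li <- log(intensity)
  lo <- unname(quantile(li, clip_quantiles[1]))
  hi <- unname(quantile(li, 1 - clip_quantiles[2]))
  if (hi <= lo) abort("Dye intensities are constant (after clipping): no core-periphery axis.")
  pmin(pmax((li - lo) / (hi - lo), 0), 1)
}

#' Add radial positions to a cell metadata table
#'
#' Convenience wrapper around [compute_radial_position()]: reads the dye
#' intensity column and appends a `radial_position` column. Rows that already
#' have a radial position are overwritten.
#'
#' @param cells Data frame with one row per cell, containing
#'   `intensity_col`.
#' @param intensity_col Name of the dye intensity column.
#' @inheritParams compute_radial_position
#' @return `cells` as a tibble with a `radial_position` column.
#' @export
add_radial_position <- function(cells, intensity_col = "calcein_intensity",
                                clip_quantiles = c(0, 0)) {
  cells <- tibble::as_tibble(cells)
  if (!intensity_col %in% names(cells)) {
    abort(sprintf("Column `%s` not found in `cells`.", intensity_col))
  }
  inten <- setNames(cells[[intensity_col]], cells$cell_id)
  dplyr::mutate(cells, radial_position = unname(compute_radial_position(inten, clip_quantiles)))
}

#' Quality-control filter on cells
#'
#' Retains cells with at least `min_depth` total UMIs and at least
#' `min_genes_detected` genes with a non-zero count, and subsets the count
#' matrix to the retained cells. Defaults are deliberately conservative for
#' deep plate-based data and should be adapted to the protocol at hand.
#'
#' @param cells Cell metadata tibble (`cell_id`, `total_umis`, ...).
#' @param counts Genes x cells count matrix with ids matching `cells`.
#' @param min_depth Minimum total UMIs per cell.
#' @param min_genes_detected Minimum number of detected (count > 0) genes.
#' @return List with elements `cells`, `counts` (both filtered), and
#'   `n_dropped`.
#' @export
qc_filter_cells <- function(cells, counts, min_depth = 10000,
                            min_genes_detected = 2000) {
  cells <- validate_cells(cells, need_position = FALSE)
  counts <- validate_counts(counts, cells)
  keep <- cells$total_umis >= min_depth &
    Matrix::colSums(counts > 0) >= min_genes_detected
  if (!any(keep)) abort("QC removed all cells; lower `min_depth` / `min_genes_detected`.")
  inform(sprintf("QC: retained %d / %d cells (%d dropped).",
                 sum(keep), length(keep), sum(!keep)))
  list(cells = cells[keep, , drop = FALSE],
       counts = counts[, keep, drop = FALSE],
       n_dropped = sum(!keep))
}

#' Restrict the gene universe to adequately expressed genes
#'
#' Keeps genes whose mean UMI count across cells is at least
#' `min_mean_umis`. One UMI per cell on average (the default) is the point
#' below which a gene cannot be expected to be quantifiable in individual
#' cells without borrowing information across cells.
#'
#' @param counts Genes x cells count matrix.
#' @param min_mean_umis Minimum mean UMIs per cell (inclusive).
#' @return The subset count matrix; warns when no gene survives.
#' @export
filter_expressed_genes <- function(counts, min_mean_umis = 1) {
  counts <- validate_counts(counts)
  keep <- Matrix::rowMeans(counts) >= min_mean_umis
  if (!any(keep)) warn("No gene passes the expression filter; returning an empty matrix.")
  counts[keep, , drop = FALSE]
}

#' Read a UMI count matrix
#'
#' Two plain-text dialects are supported: Matrix Market sparse triplets
#' (`counts.mtx` with sibling `genes.tsv` / `cells.tsv` id files, one id per
#' line) and a dense TSV (gene rows, cell columns, first column `gene_id`,
#' header row of cell ids).
#'
#' @param path Path to the `.mtx` or `.tsv` file.
#' @param dialect `"mtx_triplet"` or `"dense_tsv"`.
#' @param genes_file,cells_file Id files for the MTX dialect; default to
#'   `genes.tsv` / `cells.tsv` next to `path`.
#' @return Integer genes x cells matrix with gene rownames and cell colnames.
#' @export
read_counts <- function(path, dialect = c("mtx_triplet", "dense_tsv"),
                        genes_file = NULL, cells_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "mtx_triplet") {
    check_mtx_body(path)
    m <- as.matrix(Matrix::readMM(path))
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    cells_file <- cells_file %||% file.path(dirname(path), "cells.tsv")
    gene_ids <- readr::read_lines(genes_file)
    cell_ids <- readr::read_lines(cells_file)
    if (length(gene_ids) != nrow(m) || length(cell_ids) != ncol(m)) {
      abort(sprintf("Id files do not match matrix dimensions (%d x %d vs %d gene / %d cell ids).",
                    nrow(m), ncol(m), length(gene_ids), length(cell_ids)))
    }
    dimnames(m) <- list(gene_ids, cell_ids)
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (names(tb)[1] != "gene_id") abort("Dense TSV must have `gene_id` as its first column.")
    m <- as.matrix(tb[, -1, drop = FALSE])
    rownames(m) <- tb$gene_id
  }
  storage.mode(m) <- "double"
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

# Line-level validation of an MTX triplet body so malformed or fractional
# entries are reported with their line number (readMM's own errors are not).
check_mtx_body <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (!length(body)) abort(sprintf("%s: no matrix content found.", path))
  data_lines <- body[-1]  # first non-comment line is the size line
  for (i in data_lines) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 3 || anyNA(v)) {
      abort(sprintf("%s: malformed triplet at line %d: '%s'", path, i, lines[i]))
    }
    if (v[3] < 0 || v[3] != floor(v[3])) {
      abort(sprintf("%s: negative or non-integer count at line %d: '%s'", path, i, lines[i]))
    }
  }
  invisible(TRUE)
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(x))` round-trips
#' exactly for integer counts in both dialects.
#'
#' @param counts Genes x cells count matrix.
#' @param path Output `.mtx` or `.tsv` path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, dialect = c("mtx_triplet", "dense_tsv"),
                         genes_file = NULL, cells_file = NULL) {
  dialect <- match.arg(dialect)
  counts <- validate_counts(counts)
  if (dialect == "mtx_triplet") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"), path)
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    cells_file <- cells_file %||% file.path(dirname(path), "cells.tsv")
    readr::write_lines(rownames(counts), genes_file)
    readr::write_lines(colnames(counts), cells_file)
  } else {
    tb <- tibble::as_tibble(counts, rownames = "gene_id")
    readr::write_tsv(tb, path, progress = FALSE)
  }
  invisible(path)
}

#' Read cell metadata
#'
#' Tab-separated, one row per cell. Required columns: `cell_id`,
#' `total_umis`, and either `radial_position` or `calcein_intensity` (in the
#' latter case call [add_radial_position()] afterwards).
#'
#' @param path Path to the TSV file.
#' @return Tibble of cell profiles.
#' @export
read_cell_metadata <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cells <- validate_cells(cells, need_position = FALSE)
  if (!any(c("radial_position", "calcein_intensity") %in% names(cells))) {
    abort("Cell metadata needs `radial_position` or `calcein_intensity`.")
  }
  if ("radial_position" %in% names(cells)) validate_cells(cells) else cells
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped (first occurrence kept); set order is
#' preserved.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `set_name`, `description`, and a list-column
#'   `genes` of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("%s: empty GMT file; returning an empty collection.", path))
    return(tibble::tibble(set_name = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("%s: GMT line %d has fewer than 3 tab-separated fields.", path, bad[1]))
  }
  out <- tibble::tibble(
    set_name = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(out$set_name)) abort(sprintf("%s: duplicated set names.", path))
  out
}
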