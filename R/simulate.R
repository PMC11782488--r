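# Synthetic spheroid data with known ground truth. The generator emulates
# the study conditions of dye-diffusion-positioned deep single-cell
# transcriptomics: cell density growing quadratically with radial position
# (spherical shells), lognormal sequencing depths, and per-gene negative
# binomial UMI counts with mean f(r) * depth.

#' Sample radial positions with spherical-shell geometry
#'
#' In a solid sphere the number of cells at radial position `r` grows as
#' `r^2`, so positions are drawn by inverse-CDF sampling: `r = U^(1/3)` with
#' `U ~ Uniform(0, 1)`; equivalently `r^3` is uniform.
#'
#' @param n Number of cells.
#' @param seed Optional integer seed.
#' @return Vector of radial positions in `[0, 1]`.
#' @export
sample_radial_positions <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed_maybe(seed, runif(n)^(1 / 3))
}

#' Sample per-cell sequencing depths
#'
#' Lognormal with the stated median (`meanlog = log(median_depth)`), rounded
#' to integers and floored at 100 UMIs.
#'
#' @param n Number of cells.
#' @param median_depth Target median total UMIs per cell (`>= 100`).
#' @param log_sd Standard deviation of log depth.
#' @param seed Optional integer seed.
#' @return Integer vector of depths.
#' @export
sample_depths <- function(n, median_depth, log_sd, seed = NULL) {
  stopifnot(median_depth >= 100, log_sd >= 0)
  with_seed_maybe(seed, pmax(round(rlnorm(n, log(median_depth), log_sd)), 100))
}

#' Simulation configuration
#'
#' Gene blocks prescribe, per spatial pattern, how many genes to plant and
#' the ranges their peak fractional abundance, regulation magnitude, and
#' negative binomial size are drawn from (log-uniform for abundance and
#' size, uniform for magnitude). The default emulates a deep plate-based
#' spheroid run scaled to desktop size: 1,500 cells, median depth 20,000
#' UMIs, 300 spatially regulated genes (core-heavy, as observed in
#' spheroids) and 300 unregulated genes.
#'
#' @param n_cells Number of cells (`>= 50`).
#' @param median_depth Median UMIs per cell.
#' @param depth_log_sd Lognormal sd of depths.
#' @param gene_blocks Tibble with columns `pattern`
#'   (`core|periphery|intermediate|extrema|flat`), `n_genes`, `a_min`,
#'   `a_max` (peak fractional abundance), `mag_min`, `mag_max`,
#'   `theta_min`, `theta_max`.
#' @param seed Integer seed driving all draws.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1500, median_depth = 2e4,
                              depth_log_sd = 0.4,
                              gene_blocks = default_gene_blocks(),
                              seed = 1) {
  stopifnot(n_cells >= 50, median_depth >= 100)
  gene_blocks <- tibble::as_tibble(gene_blocks)
  req <- c("pattern", "n_genes", "a_min", "a_max", "mag_min", "mag_max",
           "theta_min", "theta_max")
  miss <- setdiff(req, names(gene_blocks))
  if (length(miss)) abort(paste0("gene_blocks missing: ", paste(miss, collapse = ", ")))
  ok <- gene_blocks$pattern %in% c("core", "periphery", "intermediate", "extrema", "flat")
  if (!all(ok)) abort("Unknown pattern in gene_blocks.")
  if (any(gene_blocks$mag_min < 0 | gene_blocks$mag_max >= 1)) {
    abort("Magnitudes must lie in [0, 1).")
  }
  structure(list(n_cells = as.integer(n_cells), median_depth = median_depth,
                 depth_log_sd = depth_log_sd, gene_blocks = gene_blocks,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_gene_blocks <- function() {
  tibble::tribble(
    ~pattern,       ~n_genes, ~a_min, ~a_max, ~mag_min, ~mag_max, ~theta_min, ~theta_max,
    "core",         90L,      5e-5,   1e-3,   0.3,      0.8,      1,          20,
    "periphery",    90L,      5e-5,   1e-3,   0.3,      0.8,      1,          20,
    "intermediate", 60L,      5e-5,   1e-3,   0.3,      0.8,      1,          20,
    "extrema",      60L,      5e-5,   1e-3,   0.3,      0.8,      1,          20,
    "flat",         300L,     5e-5,   1e-3,   0,        0,        1,          20
  )
}

# Convert (f(0), f(0.5), f(1)) anchors to polynomial coefficients. Anchored
# construction guarantees positivity at the anchors; positivity on all of
# [0, 1] is then checked analytically.
anchors_to_coef <- function(f0, fm, f1) {
  c <- 2 * f0 + 2 * f1 - 4 * fm
  b <- 4 * fm - 3 * f0 - f1
  list(a = f0, b = b, c = c)
}

# Truth parameters for one gene of a given pattern, peak abundance, and
# magnitude. Core/periphery genes are linear; intermediate/extrema genes are
# symmetric parabolas with vertex at r = 0.5.
truth_coef <- function(pattern, a_peak, mag) {
  low <- a_peak * (1 - mag)
  switch(pattern,
    flat = list(a = a_peak, b = 0, c = 0),
    core = list(a = a_peak, b = -a_peak * mag, c = 0),
    periphery = list(a = low, b = a_peak * mag, c = 0),
    intermediate = anchors_to_coef(low, a_peak, low),
    extrema = anchors_to_coef(a_peak, low, a_peak),
    abort(sprintf("Unknown pattern '%s'.", pattern)))
}

#' Build the ground-truth gene table for a simulation
#'
#' Draws per-gene truth parameters from the configured blocks and verifies
#' that each regulation function is positive on `[0, 1]`, that the stored
#' magnitude equals [regulation_magnitude()] of the stored coefficients,
#' and that peak fractional abundances sum to at most 1.
#'
#' @param config A [simulation_config()].
#' @return Tibble: `gene_id`, `pattern`, `a`, `b`, `c`, `theta`,
#'   `magnitude`.
#' @export
make_truth_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_maybe(config$seed + 2L, {
    rows <- purrr::pmap_dfr(config$gene_blocks, function(pattern, n_genes, a_min,
                                                         a_max, mag_min, mag_max,
                                                         theta_min, theta_max) {
      a_peak <- loguniform(n_genes, a_min, a_max)
      mag <- runif(n_genes, mag_min, mag_max)
      theta <- loguniform(n_genes, theta_min, theta_max)
      co <- purrr::map2(seq_len(n_genes), mag, function(i, m) truth_coef(pattern, a_peak[i], m))
      tibble::tibble(pattern = pattern,
                     a = purrr::map_dbl(co, "a"), b = purrr::map_dbl(co, "b"),
                     c = purrr::map_dbl(co, "c"), theta = theta, magnitude = mag,
                     a_peak = a_peak)
    })
  })
  rows <- dplyr::mutate(rows,
                        gene_id = sprintf("gene_%04d", dplyr::row_number()),
                        .before = 1)
  rng <- regulation_range(rows$a, rows$b, rows$c)
  if (any(rng$min <= 0)) abort("Infeasible gene block: regulation function non-positive on [0, 1].")
  stopifnot(max(abs((1 - rng$min / rng$max) - rows$magnitude)) < 1e-12)
  if (sum(rows$a_peak) > 1) {
    abort("Gene blocks infeasible: peak fractional abundances sum above 1.")
  }
  dplyr::select(rows, -"a_peak")
}

#' Simulate a UMI count matrix from ground-truth regulation functions
#'
#' Draws `n_gc ~ NB(mean = f_g(r_c) * N_c, size = theta_g)` independently
#' across genes and cells (the gamma-Poisson mixture R's `rnbinom`
#' implements).
#'
#' @param cells Cell metadata with `radial_position` and `total_umis`.
#' @param truth Truth table with `gene_id`, `a`, `b`, `c`, `theta` (e.g.
#'   from [make_truth_table()]).
#' @param seed Optional integer seed.
#' @return Integer genes x cells count matrix.
#' @export
simulate_counts <- function(cells, truth, seed = NULL) {
  cells <- validate_cells(cells)
  rng <- regulation_range(truth$a, truth$b, truth$c)
  if (any(rng$min <= 0)) abort("Truth entry with non-positive regulation function.")
  r <- cells$radial_position
  N <- cells$total_umis
  with_seed_maybe(seed, {
    m <- matrix(0L, nrow = nrow(truth), ncol = nrow(cells),
                dimnames = list(truth$gene_id, cells$cell_id))
    for (g in seq_len(nrow(truth))) {
      mu <- (truth$a[g] + truth$b[g] * r + truth$c[g] * r^2) * N
      m[g, ] <- as.integer(rnbinom(length(mu), mu = mu, size = truth$theta[g]))
    }
    m
  })
}

#' Posterior-predictive simulation for one fitted gene
#'
#' Draws counts from the fitted negative binomial at each cell's observed
#' radial position and depth. Overlaying these on the observed counts (or
#' comparing binned means) checks that the inferred regulation function is
#' consistent with the data it was fit to.
#'
#' @param fit A converged [fit_gene()] result.
#' @param cells Cell metadata the gene was fit on.
#' @param seed Optional integer seed.
#' @return Tibble: `cell_id`, `radial_position`, `total_umis`, `mu`,
#'   `simulated`.
#' @export
posterior_predictive <- function(fit, cells, seed = NULL) {
  if (!inherits(fit, "regulation_fit")) abort("`fit` must be a regulation_fit.")
  if (!fit$converged) abort("Cannot simulate from an unconverged fit.")
  cells <- validate_cells(cells)
  mu <- pmax(eval_regulation(fit$coef[["a"]], fit$coef[["b"]], fit$coef[["c"]],
                             cells$radial_position) * cells$total_umis, 1e-12)
  sim <- with_seed_maybe(seed, rnbinom(length(mu), mu = mu, size = fit$theta))
  tibble::tibble(cell_id = cells$cell_id, radial_position = cells$radial_position,
                 total_umis = cells$total_umis, mu = mu, simulated = sim)
}

#' Generate a complete benchmark dataset with ground truth
#'
#' End-to-end synthetic dataset: radial positions with spherical-shell
#' geometry, lognormal depths, truth table from the configured gene blocks,
#' and NB counts. Truth pattern labels agree with [classify_pattern()]
#' applied to the true coefficients. Optionally writes
#' `counts.mtx`/`genes.tsv`/`cells.tsv`/`cells_metadata.tsv`/`truth.tsv`
#' to a directory.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return List with `cells` (tibble), `counts` (matrix), `truth` (tibble).
#' @export
make_benchmark <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- with_seed_maybe(config$seed, {
    tibble::tibble(
      cell_id = sprintf("cell_%04d", seq_len(config$n_cells)),
      radial_position = sample_radial_positions(config$n_cells),
      total_umis = sample_depths(config$n_cells, config$median_depth,
                                 config$depth_log_sd))
  })
  truth <- make_truth_table(config)
  check <- purrr::pmap_chr(truth[, c("a", "b", "c", "pattern")],
                           function(a, b, c, pattern) {
                             classify_pattern(a, b, c, b_sig = b != 0, c_sig = c != 0,
                                              called = pattern != "flat")
                           })
  stopifnot(identical(check, ifelse(truth$pattern == "flat", "flat", truth$pattern)))
  counts <- simulate_counts(cells, truth, seed = config$seed + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(counts, file.path(out_dir, "counts.mtx"))
    readr::write_tsv(cells, file.path(out_dir, "cells_metadata.tsv"), progress = FALSE)
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  list(cells = cells, counts = counts, truth = truth)
}
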