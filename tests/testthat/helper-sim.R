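# Fixtures built in code: small cell tables and benchmark configurations.

make_cells <- function(n, median_depth = 2e4, log_sd = 0.4, seed = 1,
                       spherical = TRUE) {
  withr::with_seed(seed, {
    r <- if (spherical) runif(n)^(1 / 3) else runif(n)
    tibble::tibble(
      cell_id = sprintf("c%05d", seq_len(n)),
      radial_position = r,
      total_umis = pmax(round(rlnorm(n, log(median_depth), log_sd)), 100))
  })
}

# A small but adequately powered benchmark configuration.
small_blocks <- function(n_core = 10, n_periph = 10, n_inter = 5, n_extr = 5,
                         n_flat = 20, mag_min = 0.5, mag_max = 0.7) {
  tibble::tribble(
    ~pattern,       ~n_genes,            ~a_min, ~a_max, ~mag_min, ~mag_max, ~theta_min, ~theta_max,
    "core",         as.integer(n_core),  1e-4,   5e-4,   mag_min,  mag_max,  2,          10,
    "periphery",    as.integer(n_periph),1e-4,   5e-4,   mag_min,  mag_max,  2,          10,
    "intermediate", as.integer(n_inter), 1e-4,   5e-4,   mag_min,  mag_max,  2,          10,
    "extrema",      as.integer(n_extr),  1e-4,   5e-4,   mag_min,  mag_max,  2,          10,
    "flat",         as.integer(n_flat),  1e-4,   5e-4,   0,        0,        2,          10)
}

# Tiny deterministic count matrix with matching cell table.
toy_counts <- function() {
  m <- matrix(c(3L, 2L, 0L,
                1L, 0L, 4L),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  cells <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                          radial_position = c(0.1, 0.5, 0.9),
                          total_umis = c(50L, 40L, 60L))
  list(counts = m, cells = cells)
}
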