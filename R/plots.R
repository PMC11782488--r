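# ggplot2 diagnostics: per-gene fit overlays, pattern summaries,
# downsampling saturation, pathway positional profiles.

#' Diagnostic plot of a fitted gene
#'
#' Observed UMI counts against radial position, the fitted mean curve
#' `f(r) * N` (drawn at the median depth), and, optionally, a
#' posterior-predictive cloud of counts simulated from the fit -- the
#' visual check that the inferred regulation function is consistent with
#' the data.
#'
#' @param fit A [fit_gene()] result.
#' @param counts Observed counts for this gene, one per cell.
#' @param cells Cell metadata with radial positions and depths.
#' @param predictive Overlay a [posterior_predictive()] simulation?
#' @param seed Seed for the predictive draw.
#' @return A ggplot object.
#' @export
plot_gene_fit <- function(fit, counts, cells, predictive = TRUE, seed = 1) {
  cells <- validate_cells(cells)
  df <- tibble::tibble(r = cells$radial_position, n = counts)
  med_n <- median(cells$total_umis)
  curve <- tibble::tibble(r = seq(0, 1, length.out = 101))
  curve$mu <- eval_regulation(fit$coef[["a"]], fit$coef[["b"]], fit$coef[["c"]],
                              curve$r) * med_n
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$n))
  if (predictive && fit$converged) {
    sim <- posterior_predictive(fit, cells, seed = seed)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(r = sim$radial_position, n = sim$simulated),
      color = "grey70", size = 0.6, alpha = 0.6)
  }
  p +
    ggplot2::geom_point(size = 0.7, alpha = 0.7, color = "#2c5aa0") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$mu),
                       color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "radial position r (0 = core, 1 = periphery)",
                  y = "UMIs per cell",
                  title = fit$gene_id,
                  subtitle = sprintf("f(r) = %.2g + %.2g r + %.2g r^2, theta = %.2g",
                                     fit$coef[["a"]], fit$coef[["b"]],
                                     fit$coef[["c"]], fit$theta)) +
    ggplot2::theme_minimal()
}

#' @describeIn call_spatial_genes Bar chart of spatial pattern counts.
#' @param object A `sphereg_calls` table.
#' @method autoplot sphereg_calls
#' @export
autoplot.sphereg_calls <- function(object, ...) {
  df <- dplyr::count(dplyr::filter(tibble::as_tibble(object), .data$spatial),
                     .data$pattern)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c5aa0") +
    ggplot2::labs(x = "spatial pattern", y = "genes called spatial") +
    ggplot2::theme_minimal()
}

#' Plot a downsampling saturation curve
#'
#' @param curve Output of [downsampling_curve()].
#' @return A ggplot object.
#' @export
plot_downsampling_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$p, y = .data$n_spatial_genes)) +
    ggplot2::geom_line(color = "#2c5aa0") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "UMI retention probability p",
                  y = "spatial genes called") +
    ggplot2::theme_minimal()
}

#' Binned positional profile of a pathway
#'
#' Mean pathway fraction per radial bin with the `avgR` summary marked.
#'
#' @param counts,cells,geneset As in [pathway_fraction_per_cell()].
#' @param n_bins Number of radial bins.
#' @param set_name Plot title.
#' @return A ggplot object.
#' @export
plot_pathway_profile <- function(counts, cells, geneset, n_bins = 10,
                                 set_name = "pathway") {
  cells <- validate_cells(cells)
  frac <- pathway_fraction_per_cell(counts, cells, geneset, set_name)
  r <- cells$radial_position
  bin <- cut(r, breaks = seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  df <- tibble::tibble(rbar = as.vector(tapply(r, bin, mean)),
                       fbar = as.vector(tapply(frac, bin, mean)))
  df <- df[!is.na(df$rbar), ]
  avg <- avg_radial_position(frac, r, n_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rbar, y = .data$fbar)) +
    ggplot2::geom_col(width = 0.08, fill = "#2c5aa0") +
    ggplot2::geom_vline(xintercept = avg, color = "firebrick", linetype = 2) +
    ggplot2::labs(x = "radial position r", y = "mean pathway fraction",
                  title = set_name, subtitle = sprintf("avgR = %.2f", avg)) +
    ggplot2::theme_minimal()
}
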