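# Non-parametric pathway-level spatial association. Summing UMIs over a
# pathway's member genes reduces expression noise by the law of large
# numbers, so association with radial position can be tested without a
# parametric regulation function, using Chatterjee's Xi correlation.

#' Fractional pathway abundance per cell
#'
#' For each cell, the UMIs of the member genes present in the matrix are
#' summed and divided by the cell's total UMI count: the fraction of the
#' cell's transcriptome devoted to the pathway.
#'
#' @param counts Genes x cells count matrix.
#' @param cells Cell metadata (`total_umis` supplies the denominator).
#' @param geneset Character vector of member gene ids.
#' @param set_name Used in error messages.
#' @return Numeric vector, one fraction in `[0, 1]` per cell.
#' @export
pathway_fraction_per_cell <- function(counts, cells, geneset,
                                      set_name = "gene set") {
  cells <- validate_cells(cells, need_position = FALSE)
  counts <- validate_counts(counts, cells)
  members <- intersect(geneset, rownames(counts))
  if (!length(members)) {
    abort(sprintf("No member of %s is present in the count matrix.", set_name))
  }
  unname(Matrix::colSums(counts[members, , drop = FALSE]) / cells$total_umis)
}

#' Drop gene sets with too few genes in the dataset
#'
#' Small sets do not benefit from the noise averaging that motivates
#' pathway-level testing; sets with fewer than `min_genes` members present
#' in the matrix's gene universe are removed.
#'
#' @param genesets Collection from [read_gmt()] (tibble with `set_name`,
#'   `genes` list-column).
#' @param counts Count matrix defining the gene universe.
#' @param min_genes Minimum member genes present (inclusive).
#' @return Filtered collection with an added `n_genes_present` column.
#' @export
filter_genesets <- function(genesets, counts, min_genes = 5) {
  counts <- validate_counts(counts)
  genesets <- tibble::as_tibble(genesets)
  genesets$n_genes_present <-
    vapply(genesets$genes, function(g) length(intersect(g, rownames(counts))), 0L)
  dplyr::filter(genesets, .data$n_genes_present >= min_genes)
}

#' Chatterjee's Xi correlation
#'
#' Rank-based coefficient of the dependence of `y` on `x`, sensitive to
#' arbitrary -- including non-monotone -- functional relationships. With
#' observations sorted by `x` (ties broken at random, seeded), the
#' tie-aware statistic is
#' `xi = 1 - n * sum |r_(i+1) - r_i| / (2 * sum l_i (n - l_i))` with
#' `r_i = #\{j: y_j <= y_i\}` and `l_i = #\{j: y_j >= y_i\}`. Without ties
#' the null satisfies `sqrt(n) * xi -> N(0, 2/5)`, which supplies the
#' (one-sided) asymptotic p-value; for small samples or heavy ties a seeded
#' permutation p-value is used instead.
#'
#' @param x,y Equal-length numeric vectors (`n >= 3`).
#' @param p_method `"auto"` (asymptotic when `n >= 100` and ties affect
#'   fewer than 10% of values, else permutation), `"asymptotic"`, or
#'   `"permutation"`.
#' @param n_perm Permutation count.
#' @param seed Optional integer seed (tie-breaking and permutations).
#' @return List with `xi` and `p`.
#' @export
xi_correlation <- function(x, y, p_method = c("auto", "asymptotic", "permutation"),
                           n_perm = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  if (length(unique(y)) == 1) return(list(xi = 0, p = 1))
  with_seed_maybe(seed, {
    xi <- xi_stat(x, y)
    tie_frac <- 1 - length(unique(y)) / n
    use_asymp <- p_method == "asymptotic" ||
      (p_method == "auto" && n >= 100 && tie_frac < 0.1)
    p <- if (use_asymp) {
      pnorm(sqrt(n) * xi, mean = 0, sd = sqrt(2 / 5), lower.tail = FALSE)
    } else {
      null <- replicate(n_perm, xi_stat(x, y[sample.int(n)]))
      (1 + sum(null >= xi)) / (n_perm + 1)
    }
    list(xi = xi, p = p)
  })
}

# The statistic alone (random tie-break in x uses the current RNG stream).
xi_stat <- function(x, y) {
  n <- length(x)
  ord <- order(x, sample.int(n))
  ys <- y[ord]
  rr <- rank(ys, ties.method = "max")          # r_i = #{ y_j <= y_i }
  ll <- n + 1 - rank(ys, ties.method = "min")  # l_i = #{ y_j >= y_i }
  1 - n * sum(abs(diff(rr))) / (2 * sum(ll * (n - ll)))
}

#' Abundance-weighted average radial position of a pathway
#'
#' Cells are binned into `n_bins` equal-width, right-closed radial bins on
#' `[0, 1]`; within each non-empty bin the mean radial position and mean
#' pathway fraction are computed, and `avgR` is the fraction-weighted mean
#' of the bin positions: `sum_b rbar_b fbar_b / sum_b fbar_b`. A pathway
#' expressed mostly near the periphery has `avgR` close to 1.
#'
#' @param fraction Pathway fraction per cell ([pathway_fraction_per_cell()]).
#' @param r Radial positions, same length.
#' @param n_bins Number of bins (`>= 2`).
#' @return `avgR` in `[0, 1]`.
#' @export
avg_radial_position <- function(fraction, r, n_bins = 10) {
  stopifnot(length(fraction) == length(r), n_bins >= 2)
  check_prob(r, "r")
  if (all(fraction == 0)) abort("All pathway fractions are zero: avgR undefined.")
  bin <- cut(r, breaks = seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  rbar <- tapply(r, bin, mean)
  fbar <- tapply(fraction, bin, mean)
  keep <- !is.na(rbar)
  sum(rbar[keep] * fbar[keep]) / sum(fbar[keep])
}

#' Scan gene sets for spatial association
#'
#' For every set in a (pre-filtered) collection, computes the per-cell
#' pathway fraction, the Xi correlation of the fraction against radial
#' position with its p-value, BH q-values across sets, the significance
#' call at `q < fdr_max`, and the `avgR` positional summary.
#'
#' @param counts Genes x cells count matrix.
#' @param cells Cell metadata with radial positions.
#' @param genesets Collection from [read_gmt()].
#' @param min_genes Minimum member genes present per set.
#' @param fdr_max FDR threshold for the significance call.
#' @param n_bins Bins for [avg_radial_position()].
#' @param seed Integer seed (Xi tie-breaking / permutations).
#' @param ... Passed to [xi_correlation()].
#' @return Tibble: `set_name`, `n_genes_present`, `xi`, `p`, `q`,
#'   `significant`, `avgR`.
#' @export
pathway_spatial_scan <- function(counts, cells, genesets, min_genes = 5,
                                 fdr_max = 0.1, n_bins = 10, seed = 1, ...) {
  cells <- validate_cells(cells)
  counts <- validate_counts(counts, cells)
  genesets <- filter_genesets(genesets, counts, min_genes)
  if (!nrow(genesets)) abort("No gene set has enough member genes in the matrix.")
  r <- cells$radial_position
  res <- purrr::map_dfr(seq_len(nrow(genesets)), function(i) {
    frac <- pathway_fraction_per_cell(counts, cells, genesets$genes[[i]],
                                      genesets$set_name[i])
    xc <- xi_correlation(r, frac, seed = seed + i, ...)
    tibble::tibble(set_name = genesets$set_name[i],
                   n_genes_present = genesets$n_genes_present[i],
                   xi = xc$xi, p = xc$p,
                   avgR = if (all(frac == 0)) NA_real_
                          else avg_radial_position(frac, r, n_bins))
  })
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < fdr_max
  dplyr::relocate(res, "q", "significant", .after = "p")
}

#' Confound-adjusted spatial regression
#'
#' Spatial expression differences could in principle reflect intrinsic cell
#' states (cell cycle, stress) that happen to vary with position rather
#' than position itself. For each gene this fits two negative binomial
#' regressions with a log sequencing-depth offset: counts on radial
#' position alone (raw) and counts on radial position plus log-transformed
#' cell-cycle and stress signature scores (adjusted), and returns both
#' position coefficients. A raw/adjusted correlation near 1 across genes
#' indicates spatial signal is not explained by the intrinsic states.
#'
#' @param counts Genes x cells count matrix (fit on all rows).
#' @param cells Cell metadata with radial positions.
#' @param cellcycle_genes,stress_genes Signature gene id vectors (may be
#'   empty, in which case the adjusted model equals the raw model, with a
#'   warning).
#' @param pseudocount Added to signature fractions before log transform;
#'   defaults to `1 / median(total_umis)`.
#' @return Tibble of class `sphereg_confounds`: `gene_id`,
#'   `space_coef_raw`, `space_coef_adjusted`; the across-gene Pearson
#'   correlation of the two is in `attr(, "coef_correlation")` and in
#'   [glance()].
#' @export
regress_confounds <- function(counts, cells, cellcycle_genes = character(),
                              stress_genes = character(), pseudocount = NULL) {
  cells <- validate_cells(cells)
  counts <- validate_counts(counts, cells)
  pseudocount <- pseudocount %||% 1 / median(cells$total_umis)
  score <- function(genes, label) {
    if (!length(intersect(genes, rownames(counts)))) return(NULL)
    log(pathway_fraction_per_cell(counts, cells, genes, label) + pseudocount)
  }
  cc <- score(cellcycle_genes, "cell-cycle signature")
  st <- score(stress_genes, "stress signature")
  if (is.null(cc) && is.null(st)) {
    warn("No signature genes present: adjusted coefficients equal raw coefficients.")
  }
  covars <- list(cc_score = cc, stress_score = st)
  covars <- covars[!vapply(covars, is.null, TRUE)]
  # constant covariates carry no information and break the fit
  degen <- vapply(covars, function(v) sd(v) == 0, TRUE)
  if (any(degen)) {
    warn(paste0("Dropping constant covariate(s): ", paste(names(covars)[degen], collapse = ", ")))
    covars <- covars[!degen]
  }
  df <- tibble::tibble(r = cells$radial_position,
                       off = log(cells$total_umis), !!!covars)
  rhs_adj <- paste(c("r", names(covars)), collapse = " + ")
  fit_coef <- function(y, rhs) {
    dat <- cbind(df, y = y)
    fml <- stats::as.formula(paste0("y ~ ", rhs, " + offset(off)"))
    out <- tryCatch(
      suppressWarnings(MASS::glm.nb(fml, data = dat)),
      error = function(e) NULL)
    if (is.null(out)) NA_real_ else unname(coef(out)[["r"]])
  }
  res <- purrr::map_dfr(rownames(counts), function(g) {
    y <- counts[g, ]
    tibble::tibble(gene_id = g,
                   space_coef_raw = fit_coef(y, "r"),
                   space_coef_adjusted = if (length(covars)) fit_coef(y, rhs_adj)
                                         else NA_real_)
  })
  if (!length(covars)) res$space_coef_adjusted <- res$space_coef_raw
  ok <- complete.cases(res[, c("space_coef_raw", "space_coef_adjusted")])
  rho <- if (sum(ok) >= 3) cor(res$space_coef_raw[ok], res$space_coef_adjusted[ok])
         else NA_real_
  structure(res, class = c("sphereg_confounds", class(res)), coef_correlation = rho)
}

#' @rdname regress_confounds
#' @param x A `sphereg_confounds` table.
#' @param ... Unused.
#' @method glance sphereg_confounds
#' @export
glance.sphereg_confounds <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 coef_correlation = attr(x, "coef_correlation"))
}
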