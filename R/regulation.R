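# Core model: per-gene spatial regulation f(r) = a + b r + c r^2 inferred
# from UMI counts under a negative binomial observation model,
#   n_gc ~ NB(mean = f_g(r_c) * N_c, size = theta_g),
# where r_c is the cell's radial position and N_c its sequencing depth.

#' Evaluate a spatial regulation function
#'
#' The fractional abundance of a gene at radial position `r` is modeled as a
#' second-order polynomial `f(r) = a + b r + c r^2`: `a` is the fractional
#' abundance at the spheroid core, `b` the linear and `c` the quadratic
#' trend towards the periphery. `f` must be positive wherever evaluated (a
#' fraction of the transcriptome cannot be negative).
#'
#' @param a,b,c Polynomial coefficients.
#' @param r Radial position(s) in `[0, 1]`.
#' @return `a + b*r + c*r^2`, vectorized over `r`.
#' @examples
#' eval_regulation(2, -2, 1, 0.5)
#' @export
eval_regulation <- function(a, b = 0, c = 0, r) {
  if (any(r < 0 | r > 1)) abort("`r` must lie in [0, 1].")
  f <- a + b * r + c * r^2
  if (any(f <= 0)) abort("Regulation function is non-positive on [0, 1]: not a valid fractional abundance.")
  f
}

# Extremal values of f over [0, 1]: endpoints plus the interior vertex when
# it falls inside. Vectorized over coefficient vectors.
regulation_range <- function(a, b, c) {
  f0 <- a
  f1 <- a + b + c
  rstar <- ifelse(c != 0, -b / (2 * c), NA_real_)
  fstar <- ifelse(!is.na(rstar) & rstar > 0 & rstar < 1,
                  a + b * rstar + c * rstar^2, NA_real_)
  fmin <- pmin(f0, f1, fstar, na.rm = TRUE)
  fmax <- pmax(f0, f1, fstar, na.rm = TRUE)
  list(min = fmin, max = fmax, rstar = rstar)
}

#' Regulation magnitude of a spatial regulation function
#'
#' The relative dynamic range of `f` over the core-periphery axis:
#' `1 - min f / max f` on `[0, 1]` (default), or the fold change
#' `max f / min f`. A constant gene has magnitude 0; a gene whose minimum
#' expression is 30% below its maximum has magnitude 0.3. Extrema are found
#' analytically from the endpoints and the interior vertex.
#'
#' @inheritParams eval_regulation
#' @param method `"relative_range"` (default) or `"fold_change"`.
#' @return Magnitude, vectorized over coefficients.
#' @examples
#' regulation_magnitude(2, -2, 1)
#' @export
regulation_magnitude <- function(a, b = 0, c = 0, method = c("relative_range", "fold_change")) {
  method <- match.arg(method)
  rng <- regulation_range(a, b, c)
  if (any(rng$min <= 0)) abort("Regulation function is non-positive on [0, 1].")
  if (method == "relative_range") 1 - rng$min / rng$max else rng$max / rng$min
}

#' Negative binomial log probability mass
#'
#' Mean/size parameterization: `mu` is the expected count and `theta` the
#' size (overdispersion) parameter, with `variance = mu + mu^2/theta`;
#' `theta -> Inf` recovers the Poisson. `mu = 0` puts all mass on zero.
#'
#' @param n Non-negative integer count(s).
#' @param mu Mean(s), `>= 0`.
#' @param theta Size parameter(s), `> 0`.
#' @return Log pmf, vectorized.
#' @examples
#' nb_logpmf(0, mu = 1, theta = 1)  # log(1/2)
#' @export
nb_logpmf <- function(n, mu, theta) {
  if (any(n < 0) || any(n != floor(n))) abort("`n` must be non-negative integers.")
  if (any(mu < 0)) abort("`mu` must be >= 0.")
  if (any(theta <= 0)) abort("`theta` must be > 0.")
  dnbinom(n, mu = mu, size = theta, log = TRUE)
}

#' Weak prior for spatial regulation fits
#'
#' Two numerical pathologies of per-gene maximum likelihood are handled by
#' weak priors rather than hard constraints: (i) the likelihood is flat in
#' `a` as `f` approaches zero, so a soft log-barrier keeps
#' `min f >= epsilon / median(N)` (expression of at least `epsilon` expected
#' molecules in a median-depth cell); (ii) for genes with weak trends the
#' likelihood is flat in `b` and `c`, so both get zero-mean Gaussian
#' ("no trend") priors with scale `sigma_scale` times the gene's abundance
#' scale -- weak by construction.
#'
#' @param cells Cell metadata (for the depth scale).
#' @param a0 Abundance scale of the gene (its mean fractional abundance).
#' @param epsilon Floor, in expected molecules per median-depth cell.
#' @param sigma_scale Trend prior scale, in units of `a0`.
#' @param barrier_weight Softplus barrier weight per evaluation point.
#' @return Object of class `regulation_prior`.
#' @export
regulation_prior <- function(cells, a0, epsilon = 0.1, sigma_scale = 100,
                             barrier_weight = 100) {
  med_n <- median(cells$total_umis)
  scale <- max(a0, 1 / med_n)
  structure(list(floor_f = epsilon / med_n,
                 sigma_b = sigma_scale * scale,
                 sigma_c = sigma_scale * scale,
                 barrier_weight = barrier_weight),
            class = "regulation_prior")
}

# Numerically stable softplus.
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# Log prior density (up to a constant) at coefficients (a, b, c); the
# barrier is evaluated at the cells' radial positions plus both endpoints,
# and stays finite (linearly decreasing) even where f <= 0.
log_prior <- function(a, b, c, r, prior) {
  rb <- c(r, 0, 1)
  f <- a + b * rb + c * rb^2
  bar <- -prior$barrier_weight * sum(softplus((prior$floor_f - f) / prior$floor_f))
  bar - 0.5 * (b / prior$sigma_b)^2 - 0.5 * (c / prior$sigma_c)^2
}

#' Log posterior of a gene's spatial regulation parameters
#'
#' Sum over cells of the negative binomial log pmf of the observed counts
#' with mean `f(r_c) * N_c` and size `theta`, plus the log prior (see
#' [regulation_prior()]); `prior = NULL` gives the pure log likelihood.
#' Means are floored at a tiny positive value so the result is always
#' finite (never `NaN`), with the barrier dominating where `f` dips below
#' its floor.
#'
#' @param counts Integer UMI counts, one per cell.
#' @param cells Cell metadata with `radial_position` and `total_umis`.
#' @param params Named vector or list with `a`, `b`, `c`, `theta`.
#' @param prior A [regulation_prior()] or `NULL` for a flat prior.
#' @return Scalar log posterior (log likelihood when `prior = NULL`).
#' @export
gene_log_posterior <- function(counts, cells, params, prior = NULL) {
  cells <- validate_cells(cells)
  if (length(counts) != nrow(cells)) abort("`counts` and `cells` lengths differ.")
  a <- params[["a"]]; b <- params[["b"]]; c <- params[["c"]]
  theta <- params[["theta"]]
  if (theta <= 0) abort("`theta` must be > 0.")
  r <- cells$radial_position
  mu <- pmax((a + b * r + c * r^2) * cells$total_umis, 1e-12)
  ll <- sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
  if (is.null(prior)) ll else ll + log_prior(a, b, c, r, prior)
}

# --- internal objective for the optimizer: parameters (a, b, c, log theta) ---

negpost <- function(par, counts, r, N, prior) {
  a <- par[1]; b <- par[2]; c <- par[3]; theta <- exp(par[4])
  mu <- pmax((a + b * r + c * r^2) * N, 1e-12)
  ll <- sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
  -(ll + log_prior(a, b, c, r, prior))
}

negpost_grad <- function(par, counts, r, N, prior) {
  a <- par[1]; b <- par[2]; c <- par[3]; theta <- exp(par[4])
  f <- a + b * r + c * r^2
  mu <- pmax(f * N, 1e-12)
  # dl/dmu, zeroed where the floor is active (mu constant there)
  dmu <- (counts / mu - (counts + theta) / (theta + mu)) * N * (f * N > 1e-12)
  # barrier: d/df [-w softplus((floor - f)/floor)] = (w/floor) sigmoid((floor - f)/floor)
  rb <- c(r, 0, 1)
  fb <- a + b * rb + c * rb^2
  dbar <- (prior$barrier_weight / prior$floor_f) *
    plogis((prior$floor_f - fb) / prior$floor_f)
  ga <- sum(dmu) + sum(dbar)
  gb <- sum(dmu * r) + sum(dbar * rb) - b / prior$sigma_b^2
  gc <- sum(dmu * r^2) + sum(dbar * rb^2) - c / prior$sigma_c^2
  glt <- theta * sum(digamma(counts + theta) - digamma(theta) +
                       log(theta / (theta + mu)) + 1 - (counts + theta) / (theta + mu))
  -c(ga, gb, gc, glt)
}

#' Staged initialization for the spatial regulation fit
#'
#' Stage 1 assumes no spatial trend: `a0` is the gene's pooled fractional
#' abundance `sum(n) / sum(N)`, and the negative binomial size is estimated
#' analytically by method of moments,
#' `theta0 = sum(mu^2) / max(sum((n - mu)^2 - mu), eps)` with `mu = a0 N`,
#' clipped to `[0.01, 1e4]` (Poisson-like genes hit the upper clip). Stage 2
#' refits `(a, b)` with `c = 0` and `theta` fixed, giving the optimizer a
#' start that already captures any monotone trend.
#'
#' @inheritParams gene_log_posterior
#' @param prior A [regulation_prior()]; built from the data when `NULL`.
#' @return Named list `a`, `b`, `c`, `theta` (stage-2 values).
#' @export
init_params <- function(counts, cells, prior = NULL) {
  cells <- validate_cells(cells)
  if (nrow(cells) < 10) abort("Need at least 10 cells to initialize a fit.")
  if (sum(counts) <= 0) abort("All-zero gene: filter before fitting.")
  N <- cells$total_umis
  r <- cells$radial_position
  a0 <- sum(counts) / sum(N)
  mu <- a0 * N
  denom <- max(sum((counts - mu)^2 - mu), 1e-12)
  theta0 <- min(max(sum(mu^2) / denom, 0.01), 1e4)
  prior <- prior %||% regulation_prior(cells, a0)
  # stage 2: linear trend only, theta fixed
  obj2 <- function(p) negpost(c(p[1], p[2], 0, log(theta0)), counts, r, N, prior)
  gr2 <- function(p) negpost_grad(c(p[1], p[2], 0, log(theta0)), counts, r, N, prior)[1:2]
  o2 <- optim(c(a0, 0), obj2, gr2, method = "BFGS",
              control = list(parscale = c(a0, a0), reltol = 1e-8, maxit = 200))
  list(a = o2$par[1], b = o2$par[2], c = 0, theta = theta0)
}

#' Fit a gene's spatial regulation function (MAP + Laplace errors)
#'
#' Maximizes the log posterior of [gene_log_posterior()] over
#' `(a, b, c, log theta)` with BFGS from the [init_params()] start.
#' Standard errors are the square roots of the diagonal of the inverse
#' Hessian of the negative log posterior at the optimum (Laplace / Gauss
#' approximation). When the Hessian is not positive definite the fit is
#' flagged (`se_ok = FALSE`) and the gene is excluded from spatial calling.
#' The fit is deterministic given the inputs.
#'
#' @inheritParams init_params
#' @param gene_id Optional identifier stored in the fit.
#' @param epsilon,sigma_scale Prior settings, see [regulation_prior()].
#' @param reltol,maxit Optimizer control.
#' @return Object of class `regulation_fit`: coefficients, `theta`,
#'   standard errors (`a`, `b`, `c`, `log_theta`), log likelihood and log
#'   posterior at the MAP, convergence flags, `n_cells`.
#' @export
fit_gene <- function(counts, cells, gene_id = NA_character_,
                     epsilon = 0.1, sigma_scale = 100,
                     reltol = 1e-8, maxit = 500) {
  cells <- validate_cells(cells)
  N <- cells$total_umis
  r <- cells$radial_position
  a0 <- sum(counts) / sum(N)
  prior <- regulation_prior(cells, a0, epsilon = epsilon, sigma_scale = sigma_scale)
  st <- init_params(counts, cells, prior)
  par0 <- c(st$a, st$b, st$c, log(st$theta))
  o <- tryCatch(
    optim(par0, negpost, negpost_grad, counts = counts, r = r, N = N, prior = prior,
          method = "BFGS",
          control = list(parscale = c(a0, a0, a0, 1), reltol = reltol, maxit = maxit)),
    error = function(e) NULL)
  if (is.null(o)) {
    return(new_regulation_fit(gene_id, coef = c(a = st$a, b = st$b, c = st$c),
                              theta = st$theta, se = rep(NA_real_, 4),
                              loglik = NA_real_, logpost = NA_real_,
                              converged = FALSE, se_ok = FALSE, n_cells = nrow(cells)))
  }
  se <- rep(NA_real_, 4)
  se_ok <- FALSE
  # Hessian of the negative log posterior by central differences of the
  # analytic gradient, with steps scaled to each parameter's magnitude
  # (a, b, c live on the abundance scale; log theta on the unit scale).
  H <- laplace_hessian(o$par, counts, r, N, prior, scale = c(a0, a0, a0, 1))
  ch <- tryCatch(chol(H), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(ch)) {
    V <- chol2inv(ch)
    d <- diag(V)
    if (all(is.finite(d)) && all(d >= 0)) {
      se <- sqrt(d)
      se_ok <- TRUE
      vcov <- V
    }
  }
  par <- o$par
  theta <- exp(par[4])
  mu <- pmax((par[1] + par[2] * r + par[3] * r^2) * N, 1e-12)
  loglik <- sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
  new_regulation_fit(gene_id,
                     coef = c(a = par[1], b = par[2], c = par[3]),
                     theta = theta, se = se, loglik = loglik, logpost = -o$value,
                     converged = o$convergence == 0, se_ok = se_ok,
                     n_cells = nrow(cells), vcov = vcov)
}

laplace_hessian <- function(par, counts, r, N, prior, scale, rel_step = 1e-4) {
  h <- scale * rel_step
  H <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h[j]
    H[, j] <- (negpost_grad(par + e, counts, r, N, prior) -
                 negpost_grad(par - e, counts, r, N, prior)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

new_regulation_fit <- function(gene_id, coef, theta, se, loglik, logpost,
                               converged, se_ok, n_cells, vcov = NULL) {
  if (!is.null(vcov)) {
    dimnames(vcov) <- rep(list(c("a", "b", "c", "log_theta")), 2)
  }
  structure(list(gene_id = gene_id, coef = coef, theta = theta,
                 se = setNames(se, c("a", "b", "c", "log_theta")),
                 loglik = loglik, logpost = logpost,
                 converged = converged, se_ok = se_ok, n_cells = n_cells,
                 vcov = vcov),
            class = "regulation_fit")
}

#' @export
print.regulation_fit <- function(x, ...) {
  cat(sprintf("<regulation_fit> gene %s: f(r) = %.3g + %.3g r + %.3g r^2, theta = %.3g\n",
              x$gene_id, x$coef["a"], x$coef["b"], x$coef["c"], x$theta))
  cat(sprintf("  logLik %.2f over %d cells; converged: %s; SEs: %s\n",
              x$loglik, x$n_cells, x$converged,
              if (x$se_ok) "available" else "unavailable"))
  invisible(x)
}

#' @rdname fit_gene
#' @param x A `regulation_fit`.
#' @param ... Unused.
#' @method tidy regulation_fit
#' @export
tidy.regulation_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "log_theta"),
                 estimate = c(unname(x$coef), log(x$theta)),
                 std.error = unname(x$se))
}

#' @rdname fit_gene
#' @method glance regulation_fit
#' @export
glance.regulation_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logPost = x$logpost, theta = x$theta,
                 magnitude = regulation_magnitude(x$coef["a"], x$coef["b"], x$coef["c"]),
                 converged = x$converged, se_ok = x$se_ok, n_cells = x$n_cells)
}

#' Wald tests for spatial regulation
#'
#' Two-sided Wald p-values for the linear trend `b` and quadratic trend `c`
#' of a fitted gene (`p = 2 Phi(-|est|/se)`), plus a gene-level p-value for
#' "any spatial trend". On `[0, 1]` the `b` and `c` estimators are strongly
#' collinear, which deflates both per-trend z-scores even when the spatial
#' trend is unambiguous; the default gene-level test is therefore the joint
#' 2-df Wald statistic `(b, c) V^-1 (b, c)'` on the Laplace covariance
#' block, referred to a chi-square with 2 df. `method = "bonferroni"` gives
#' the per-trend combination `p_gene = min(1, 2 min(p_b, p_c))` instead,
#' which is conservative under collinearity.
#'
#' @param fit A converged [fit_gene()] result with valid standard errors.
#' @param method `"joint"` (default) or `"bonferroni"`.
#' @return Tibble with `p_b`, `p_c`, `p_gene`.
#' @export
test_spatial <- function(fit, method = c("joint", "bonferroni")) {
  method <- match.arg(method)
  if (!inherits(fit, "regulation_fit")) abort("`fit` must be a regulation_fit.")
  if (!fit$converged || !fit$se_ok) abort("Fit did not converge with valid standard errors.")
  if (any(fit$se[c("b", "c")] == 0)) abort("Degenerate fit: zero standard error.")
  p_b <- 2 * pnorm(-abs(fit$coef[["b"]]) / fit$se[["b"]])
  p_c <- 2 * pnorm(-abs(fit$coef[["c"]]) / fit$se[["c"]])
  p_gene <- if (method == "bonferroni" || is.null(fit$vcov)) {
    min(1, 2 * min(p_b, p_c))
  } else {
    bc <- fit$coef[c("b", "c")]
    W <- tryCatch(drop(crossprod(bc, solve(fit$vcov[c("b", "c"), c("b", "c")], bc))),
                  error = function(e) NA_real_)
    if (is.na(W)) min(1, 2 * min(p_b, p_c)) else pchisq(W, df = 2, lower.tail = FALSE)
  }
  tibble::tibble(p_b = p_b, p_c = p_c, p_gene = p_gene)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) m / j`. Thin,
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]` (`NA`s propagate).
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_fdr <- function(p) {
  check_prob(p[!is.na(p)], "p")
  p.adjust(p, method = "BH")
}

#' Classify the spatial pattern of a called gene
#'
#' Four patterns: `core` (expression maximal at `r = 0`), `periphery`
#' (maximal at `r = 1`), `intermediate` (interior maximum), `extrema`
#' (interior minimum, high at both ends). The interior branch requires a
#' significant quadratic trend, a vertex `r* = -b/(2c)` strictly inside
#' `[delta, 1 - delta]`, and an interior contrast
#' `|f(r*) - closer boundary| / max f >= tau`; otherwise the monotone
#' direction on `[0, 1]` decides (with a vertex exactly on the margin
#' assigned to the monotone branch). Called genes failing the contrast test
#' are `other`; genes not called spatial are `flat`.
#'
#' @inheritParams eval_regulation
#' @param b_sig,c_sig Are the linear / quadratic trends individually
#'   significant?
#' @param delta Margin excluding near-boundary vertices.
#' @param tau Minimum interior contrast relative to the maximum of `f`.
#' @param called Was the gene called spatially regulated?
#' @return One of `"core"`, `"periphery"`, `"intermediate"`, `"extrema"`,
#'   `"other"`, `"flat"`.
#' @export
classify_pattern <- function(a, b, c, b_sig, c_sig, delta = 0.1, tau = 0.1,
                             called = TRUE) {
  if (!called) return("flat")
  f0 <- a
  f1 <- a + b + c
  rstar <- if (c != 0) -b / (2 * c) else NA_real_
  interior <- isTRUE(c_sig) && !is.na(rstar) && rstar > delta && rstar < 1 - delta
  if (!interior) {
    if (f1 > f0) return("periphery")
    if (f1 < f0) return("core")
    return("other")
  }
  fstar <- a + b * rstar + c * rstar^2
  fmax <- max(f0, f1, fstar)
  closer <- if (rstar <= 0.5) f0 else f1
  if (abs(fstar - closer) / fmax < tau) return("other")
  if (c < 0) "intermediate" else "extrema"
}

#' Fit, test, and classify every gene: the spatial gene caller
#'
#' Runs [fit_gene()] on every gene of a filtered count matrix, retains genes
#' whose log likelihood at the MAP exceeds `loglik_per_cell * n_cells`
#' (poorly captured genes are excluded before testing), adjusts the
#' gene-level Wald p-values with [bh_fdr()] over the retained genes, and
#' calls a gene spatially regulated when `q < fdr_max` and its regulation
#' magnitude exceeds `mag_min`. Called genes are assigned a spatial pattern
#' with [classify_pattern()], using per-trend significance at
#' `sig_level`. The run is deterministic.
#'
#' The gene-level p-value defaults to the joint 2-df Wald test; see
#' [test_spatial()].
#'
#' @param counts Genes x cells count matrix (apply
#'   [filter_expressed_genes()] first).
#' @param cells Cell metadata with radial positions.
#' @param fdr_max FDR threshold on the BH q-value.
#' @param mag_min Minimum regulation magnitude for a spatial call.
#' @param loglik_per_cell Retention threshold on the per-cell log
#'   likelihood of the fitted model.
#' @param delta,tau Pattern classification settings, see
#'   [classify_pattern()].
#' @param sig_level Per-trend significance level used for classification.
#' @param test_method Gene-level test, see [test_spatial()].
#' @param keep_fits Keep the `regulation_fit` objects in a list-column
#'   (needed for posterior-predictive checks and fit plots).
#' @param verbose Print progress and the per-pattern summary.
#' @param ... Passed to [fit_gene()].
#' @return Tibble of class `sphereg_calls`, one row per gene: coefficients,
#'   `theta`, standard errors, `loglik`, flags, p-values, `q`, `magnitude`,
#'   `spatial`, `pattern` (and a `fit` list-column if `keep_fits`).
#' @export
call_spatial_genes <- function(counts, cells, fdr_max = 0.1, mag_min = 0.3,
                               loglik_per_cell = -4.91, delta = 0.1, tau = 0.1,
                               sig_level = 0.05, test_method = "joint",
                               keep_fits = TRUE, verbose = TRUE, ...) {
  cells <- validate_cells(cells)
  counts <- validate_counts(counts, cells)
  if (nrow(counts) == 0) abort("Empty count matrix: nothing to fit.")
  fits <- purrr::map(rownames(counts), function(g) {
    fit_gene(counts[g, ], cells, gene_id = g, ...)
  })
  tab <- purrr::map_dfr(fits, function(f) {
    tst <- if (f$converged && f$se_ok && all(f$se[c("b", "c")] > 0)) {
      test_spatial(f, method = test_method)
    } else {
      tibble::tibble(p_b = NA_real_, p_c = NA_real_, p_gene = NA_real_)
    }
    tibble::tibble(gene_id = f$gene_id,
                   a = f$coef[["a"]], b = f$coef[["b"]], c = f$coef[["c"]],
                   theta = f$theta,
                   se_a = f$se[["a"]], se_b = f$se[["b"]], se_c = f$se[["c"]],
                   se_log_theta = f$se[["log_theta"]],
                   loglik = f$loglik, converged = f$converged, se_ok = f$se_ok,
                   p_b = tst$p_b, p_c = tst$p_c, p_gene = tst$p_gene)
  })
  n_cells <- nrow(cells)
  tab <- dplyr::mutate(
    tab,
    magnitude = purrr::pmap_dbl(list(.data$a, .data$b, .data$c), function(a, b, c) {
      rng <- regulation_range(a, b, c)
      if (!is.finite(rng$min) || rng$min <= 0) return(NA_real_)
      1 - rng$min / rng$max
    }),
    retained = .data$converged & .data$se_ok & !is.na(.data$p_gene) &
      !is.na(.data$magnitude) & .data$loglik >= loglik_per_cell * n_cells
  )
  if (!any(tab$retained)) {
    abort(sprintf(paste0("No gene retained for spatial calling (%d fitted; %d converged; ",
                         "%d with valid SEs). Check depth, positions, and thresholds."),
                  nrow(tab), sum(tab$converged), sum(tab$se_ok)))
  }
  tab$q <- NA_real_
  tab$q[tab$retained] <- bh_fdr(tab$p_gene[tab$retained])
  tab <- dplyr::mutate(
    tab,
    spatial = .data$retained & .data$q < fdr_max & .data$magnitude > mag_min,
    pattern = purrr::pmap_chr(
      list(.data$a, .data$b, .data$c, .data$p_b, .data$p_c, .data$spatial),
      function(a, b, c, p_b, p_c, spatial) {
        classify_pattern(a, b, c,
                         b_sig = !is.na(p_b) && p_b < sig_level,
                         c_sig = !is.na(p_c) && p_c < sig_level,
                         delta = delta, tau = tau, called = isTRUE(spatial))
      }))
  if (keep_fits) tab$fit <- fits
  if (verbose) {
    pat <- table(tab$pattern[tab$spatial])
    inform(sprintf("Spatial calling: %d / %d genes retained; %d called spatial (%s).",
                   sum(tab$retained), nrow(tab), sum(tab$spatial),
                   paste(names(pat), as.integer(pat), sep = ": ", collapse = ", ")))
  }
  structure(tab, class = c("sphereg_calls", class(tab)),
            fdr_max = fdr_max, mag_min = mag_min,
            loglik_per_cell = loglik_per_cell, delta = delta, tau = tau,
            sig_level = sig_level, n_cells = n_cells)
}

#' @rdname call_spatial_genes
#' @param x A `sphereg_calls` table.
#' @method glance sphereg_calls
#' @export
glance.sphereg_calls <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), n_retained = sum(x$retained), n_spatial = sum(x$spatial),
    n_core = sum(x$pattern == "core"), n_periphery = sum(x$pattern == "periphery"),
    n_intermediate = sum(x$pattern == "intermediate"),
    n_extrema = sum(x$pattern == "extrema"), n_other = sum(x$pattern == "other"))
}

#' Binomial downsampling of a count matrix
#'
#' Thins every UMI count independently: `n' ~ Binomial(n, p)`, emulating a
#' shallower sequencing run with a capture probability reduced by the
#' factor `p`.
#'
#' @param counts Genes x cells count matrix.
#' @param p Retention probability in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return Thinned count matrix, same shape and dimnames.
#' @export
downsample_counts <- function(counts, p, seed = NULL) {
  counts <- validate_counts(counts)
  check_prob(p)
  with_seed_maybe(seed, {
    thin <- counts
    thin[] <- rbinom(length(counts), size = as.vector(counts), prob = p)
    thin
  })
}

#' Spatial-gene saturation under downsampling
#'
#' For each retention probability `p`, thins the matrix with
#' [downsample_counts()], rescales the per-cell depths by `p`, re-applies
#' the mean-one-UMI gene filter, and reruns the full spatial calling. The
#' number of called spatial genes as a function of `p` traces how spatial
#' signal saturates with sequencing depth.
#'
#' @inheritParams call_spatial_genes
#' @param ps Vector of retention probabilities.
#' @param seed Integer seed; each `p` uses an independent sub-seed.
#' @param min_mean_umis Gene filter re-applied after thinning.
#' @param ... Passed to [call_spatial_genes()].
#' @return Tibble with `p`, `n_genes_tested`, `n_spatial_genes`.
#' @export
downsampling_curve <- function(counts, cells, ps, seed = 1, min_mean_umis = 1, ...) {
  cells <- validate_cells(cells)
  counts <- validate_counts(counts, cells)
  purrr::map_dfr(seq_along(ps), function(i) {
    p <- ps[i]
    thin <- downsample_counts(counts, p, seed = seed + i)
    cells_p <- dplyr::mutate(cells, total_umis = pmax(1, round(.data$total_umis * p)))
    thin <- suppressWarnings(filter_expressed_genes(thin, min_mean_umis))
    if (nrow(thin) == 0) {
      return(tibble::tibble(p = p, n_genes_tested = 0L, n_spatial_genes = 0L))
    }
    res <- tryCatch(call_spatial_genes(thin, cells_p, verbose = FALSE, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(p = p, n_genes_tested = nrow(thin), n_spatial_genes = 0L)
    } else {
      tibble::tibble(p = p, n_genes_tested = nrow(thin),
                     n_spatial_genes = sum(res$spatial))
    }
  })
}
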