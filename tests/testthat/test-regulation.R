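test_that("regulation function evaluates the polynomial and guards positivity", {
  expect_equal(eval_regulation(1e-3, 0, 0, 0.7), 1e-3)
  expect_equal(eval_regulation(1e-3, 1e-3, 0, 1), 2e-3)
  expect_equal(eval_regulation(2, -2, 1, 0.5), 1.25)
  expect_error(eval_regulation(1, -3, 0, 0.5), "non-positive")
  expect_error(eval_regulation(1, 0, 0, 1.2), "\\[0, 1\\]")
})

test_that("regulation magnitude matches an independent grid minimization", {
  expect_equal(regulation_magnitude(5e-4), 0)
  expect_equal(regulation_magnitude(1, 1, 0), 0.5)
  # dense-grid oracle across random positive polynomials
  grid_mag <- function(a, b, c) {
    f <- a + b * seq(0, 1, 1e-4) + c * seq(0, 1, 1e-4)^2
    1 - min(f) / max(f)
  }
  expect_equal(regulation_magnitude(2, -2, 1), grid_mag(2, -2, 1), tolerance = 1e-6)
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- runif(1, 0.5, 2); b <- runif(1, -1, 1); c <- runif(1, -1, 1)
      if (min(a + b * c(0, 1, 0.5) + c * c(0, 1, 0.25)) <= 0.05) next
      expect_equal(regulation_magnitude(a, b, c), grid_mag(a, b, c), tolerance = 1e-6)
    }
  })
  expect_equal(regulation_magnitude(1, 1, 0, method = "fold_change"), 2)
})

test_that("NB log pmf has the right closed forms and limits", {
  expect_equal(nb_logpmf(0, mu = 1, theta = 1), log(0.5), tolerance = 1e-12)
  # theta * log(theta/(theta+mu)) at n = 0
  expect_equal(nb_logpmf(0, mu = 2.3, theta = 4), 4 * log(4 / 6.3), tolerance = 1e-12)
  # Poisson limit
  expect_equal(nb_logpmf(3, mu = 2, theta = 1e8), 3 * log(2) - 2 - log(6),
               tolerance = 1e-4)
  # degenerate mass at zero
  expect_equal(nb_logpmf(0, mu = 0, theta = 2), 0)
  expect_equal(nb_logpmf(3, mu = 0, theta = 2), -Inf)
  # normalization
  expect_equal(sum(exp(nb_logpmf(0:500, mu = 5, theta = 2))), 1, tolerance = 1e-10)
  expect_error(nb_logpmf(-1, 1, 1), "non-negative")
})

test_that("gene log posterior reduces to the likelihood under a flat prior", {
  cells1 <- tibble::tibble(cell_id = "c1", radial_position = 0.4, total_umis = 1000L)
  # single cell, n = 0, mu = 1, theta = 1
  p <- list(a = 1 / 1000, b = 0, c = 0, theta = 1)
  expect_equal(gene_log_posterior(0L, cells1, p), log(0.5), tolerance = 1e-12)
  # Poisson limit with no trend
  cells <- make_cells(200, seed = 2)
  withr::with_seed(2, counts <- rpois(200, 1e-4 * cells$total_umis))
  lp <- gene_log_posterior(counts, cells, list(a = 1e-4, b = 0, c = 0, theta = 1e8))
  pois <- sum(dpois(counts, 1e-4 * cells$total_umis, log = TRUE))
  expect_equal(lp, pois, tolerance = 1e-4)
})

test_that("the log posterior stays finite when f dips below the floor", {
  cells <- make_cells(100, seed = 9)
  counts <- rep(1L, 100)
  prior <- regulation_prior(cells, a0 = 1e-4)
  for (pars in list(list(a = -1e-4, b = 0, c = 0, theta = 2),
                    list(a = 1e-4, b = -5e-4, c = 0, theta = 2),
                    list(a = 1e-6, b = 0, c = 0, theta = 2))) {
    v <- gene_log_posterior(counts, cells, pars, prior)
    expect_true(is.finite(v))
  }
  # barrier steeply penalizes violating parameters relative to valid ones
  ok <- gene_log_posterior(counts, cells, list(a = 1e-4, b = 0, c = 0, theta = 2), prior)
  bad <- gene_log_posterior(counts, cells, list(a = -1e-4, b = 0, c = 0, theta = 2), prior)
  expect_lt(bad, ok - 1000)
})

test_that("the log posterior scales continuously with depth (no overflow)", {
  cells <- make_cells(50, median_depth = 1e6, log_sd = 0, seed = 3)
  counts <- as.integer(round(1e-3 * cells$total_umis))
  v <- gene_log_posterior(counts, cells, list(a = 1e-3, b = 0, c = 0, theta = 5),
                          regulation_prior(cells, 1e-3))
  expect_true(is.finite(v))
})

test_that("initialization recovers abundance and moment-based theta", {
  cells <- make_cells(500, log_sd = 0, seed = 4)  # constant depth 2e4
  # counts exactly proportional to depth: pooled abundance is exact, and the
  # stage-2 start stays at it with no trend to absorb
  counts <- as.integer(round(cells$total_umis * 1e-3))
  st <- init_params(counts, cells)
  expect_equal(st$a, 1e-3, tolerance = 0.02)
  expect_equal(st$c, 0)
  # underdispersed counts (zero residual variance) drive the moment
  # denominator negative, hitting the upper clip deterministically
  expect_equal(st$theta, 1e4)
  # NB-simulated gene: theta-hat lands near truth in most seeds
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      cells2 <- make_cells(2000, seed = s + 1000)
      y <- rnbinom(2000, mu = 1e-4 * cells2$total_umis, size = 2)
    })
    # stage-1 moment estimate, computed directly
    a0 <- sum(y) / sum(cells2$total_umis)
    mu <- a0 * cells2$total_umis
    th <- sum(mu^2) / max(sum((y - mu)^2 - mu), 1e-12)
    if (th >= 1 && th <= 4) hits <- hits + 1
  }
  expect_gte(hits, 90)
  expect_error(init_params(rep(0L, 500), cells), "zero")
})

test_that("a constant gene is fit with a near its pooled abundance", {
  cells <- make_cells(1000, seed = 6)
  withr::with_seed(7, counts <- rnbinom(1000, mu = 2e-4 * cells$total_umis, size = 5))
  f <- fit_gene(counts, cells, gene_id = "const")
  expect_true(f$converged && f$se_ok)
  pooled <- sum(counts) / sum(cells$total_umis)
  expect_lte(abs(f$coef[["a"]] - pooled), 3 * f$se[["a"]])
  expect_gt(f$theta, 1)
})

test_that("a spatial gene's regulation function is recovered within 30%", {
  cells <- make_cells(1500, seed = 8)
  a <- 5e-5; b <- 1e-4
  withr::with_seed(9, counts <- rnbinom(1500, mu = (a + b * cells$radial_position) *
                                          cells$total_umis, size = 5))
  f <- fit_gene(counts, cells)
  for (r in c(0, 0.5, 1)) {
    truth <- a + b * r
    est <- f$coef[["a"]] + f$coef[["b"]] * r + f$coef[["c"]] * r^2
    expect_lt(abs(est - truth) / truth, 0.3)
  }
})

test_that("fits are deterministic and tidy/glance methods are well formed", {
  cells <- make_cells(200, seed = 10)
  withr::with_seed(11, counts <- rnbinom(200, mu = 2e-4 * cells$total_umis, size = 3))
  f1 <- fit_gene(counts, cells, gene_id = "g")
  f2 <- fit_gene(counts, cells, gene_id = "g")
  expect_identical(f1$coef, f2$coef)
  expect_identical(f1$loglik, f2$loglik)
  td <- tidy(f1)
  expect_equal(td$term, c("a", "b", "c", "log_theta"))
  expect_true(all(td$std.error > 0))
  gl <- glance(f1)
  expect_true(gl$converged)
  expect_equal(gl$n_cells, 200)
})

test_that("the optimizer beats a brute-force parameter grid on small instances", {
  # 4-dimensional grid oracle on small instances; the MAP from fit_gene must
  # be at least as good as the best grid point.
  n_grid <- 8
  withr::with_seed(21, {
    for (inst in 1:3) {
      cells <- make_cells(50, seed = 30 + inst)
      a_true <- 10^runif(1, -4, -3.3)
      y <- rnbinom(50, mu = a_true * cells$total_umis, size = 3)
      if (sum(y) == 0) next
      f <- fit_gene(y, cells)
      a0 <- sum(y) / sum(cells$total_umis)
      prior <- regulation_prior(cells, a0)
      grid_best <- -Inf
      for (a in a0 * exp(seq(log(0.2), log(5), length.out = n_grid)))
        for (b in a0 * seq(-2, 2, length.out = n_grid))
          for (cc in a0 * seq(-2, 2, length.out = n_grid))
            for (th in exp(seq(log(0.1), log(100), length.out = n_grid))) {
              v <- gene_log_posterior(y, cells, list(a = a, b = b, c = cc, theta = th),
                                      prior)
              if (v > grid_best) grid_best <- v
            }
      expect_gte(f$logpost + 1e-6, grid_best)
    }
  })
})

test_that("Wald tests behave at their closed-form anchors", {
  fit <- sphereg:::new_regulation_fit(
    "g", coef = c(a = 1e-4, b = 0, c = 5e-5), theta = 2,
    se = c(1e-5, 1e-5, 1e-5, 0.1), loglik = -100, logpost = -100,
    converged = TRUE, se_ok = TRUE, n_cells = 100,
    vcov = diag(c(1e-5, 1e-5, 1e-5, 0.1)^2))
  ts <- test_spatial(fit, method = "bonferroni")
  expect_equal(ts$p_b, 1)
  fit$coef[["b"]] <- 1.959964 * 1e-5
  ts2 <- test_spatial(fit, method = "bonferroni")
  expect_equal(ts2$p_b, 0.05, tolerance = 1e-4)
  expect_equal(ts2$p_gene, min(1, 2 * min(ts2$p_b, ts2$p_c)))
  # joint test equals the chi-square of the quadratic form for diagonal vcov
  tsj <- test_spatial(fit)
  W <- (fit$coef[["b"]] / 1e-5)^2 + (fit$coef[["c"]] / 1e-5)^2
  expect_equal(tsj$p_gene, pchisq(W, 2, lower.tail = FALSE))
  fit$se[["b"]] <- 0
  expect_error(test_spatial(fit), "zero standard error")
})

test_that("gene-level p-values are valid under the null", {
  # null genes: p_gene approximately uniform (joint) / conservative (bonferroni)
  cells <- make_cells(400, seed = 12)
  pj <- pb <- numeric(60)
  for (i in 1:60) {
    withr::with_seed(100 + i,
                     y <- rnbinom(400, mu = 2e-4 * cells$total_umis, size = 5))
    f <- fit_gene(y, cells)
    if (!f$se_ok) { pj[i] <- pb[i] <- NA; next }
    pj[i] <- test_spatial(f)$p_gene
    pb[i] <- test_spatial(f, method = "bonferroni")$p_gene
  }
  expect_lte(mean(pj < 0.05, na.rm = TRUE), 0.15)
  expect_lte(mean(pb < 0.05, na.rm = TRUE), 0.15)
  # bonferroni is conservative: stochastically >= uniform
  expect_gte(mean(pb, na.rm = TRUE), 0.45)
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  q <- bh_fdr(p)
  m <- length(p)
  manual <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(q, manual)
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("patterns are classified by direction, vertex, and contrast", {
  expect_equal(classify_pattern(1e-4, 1e-4, 0, TRUE, FALSE), "periphery")
  expect_equal(classify_pattern(1e-4, -5e-5, 0, TRUE, FALSE), "core")
  expect_equal(classify_pattern(1e-4, 4e-4, -4e-4, TRUE, TRUE), "intermediate")
  # interior minimum, high at both ends
  expect_equal(classify_pattern(3e-4, -8e-4, 8e-4, TRUE, TRUE), "extrema")
  # vertex outside the margin falls back to the monotone branch
  expect_equal(classify_pattern(1e-4, 4e-4, -2.2e-4, TRUE, TRUE, delta = 0.1), "periphery")
  # vertex exactly on the margin: monotone branch (tie-break)
  a <- 1e-4
  expect_equal(classify_pattern(a, 0.2 * a, -a, TRUE, TRUE, delta = 0.1), "core")
  # weak interior contrast is 'other'
  expect_equal(classify_pattern(1e-4, 4e-5, -4e-5, TRUE, TRUE, tau = 0.5), "other")
  # insignificant quadratic falls back to monotone even with interior vertex
  expect_equal(classify_pattern(1, 4, -4, TRUE, FALSE), "other")  # f(0) = f(1) exactly
  expect_equal(classify_pattern(1e-4, 4e-4, -3e-4, TRUE, FALSE), "periphery")
  expect_equal(classify_pattern(1e-4, 1e-4, 0, TRUE, FALSE, called = FALSE), "flat")
})

test_that("spatial calling recovers planted genes and reruns identically", {
  cfg <- simulation_config(n_cells = 600, median_depth = 2e4,
                           gene_blocks = small_blocks(), seed = 42)
  bm <- make_benchmark(cfg)
  keep <- filter_expressed_genes(bm$counts)
  calls <- suppressMessages(call_spatial_genes(keep, bm$cells, keep_fits = FALSE))
  tab <- dplyr::inner_join(tibble::as_tibble(calls), bm$truth, by = "gene_id",
                           suffix = c("", "_true"))
  planted <- tab$pattern_true != "flat"
  expect_gt(mean(tab$spatial[planted]), 0.6)
  fp <- sum(tab$spatial & !planted)
  expect_lte(fp / max(1, sum(tab$spatial)), 0.2)
  calls2 <- suppressMessages(call_spatial_genes(keep, bm$cells, keep_fits = FALSE))
  expect_identical(tibble::as_tibble(calls), tibble::as_tibble(calls2))
  gl <- glance(calls)
  expect_equal(gl$n_spatial, sum(tab$spatial))
})

test_that("binomial thinning has exact endpoints and binomial moments", {
  toy <- toy_counts()
  expect_identical(downsample_counts(toy$counts, 1, seed = 1), toy$counts)
  expect_true(all(downsample_counts(toy$counts, 0, seed = 1) == 0))
  m <- matrix(10000L, 1, 1, dimnames = list("g", "c"))
  withr::with_seed(13, draws <- replicate(1000, sum(downsample_counts(m, 0.1))))
  expect_lt(abs(mean(draws) - 1000), 3 * sd(draws) / sqrt(1000) * sqrt(1000))
  expect_lt(abs(mean(draws) - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("thinning all genes leaves fitted regulation functions unchanged", {
  # fractional abundances are scale-free: thinning counts and depths by the
  # same factor must not move f-hat beyond estimation error
  cells <- make_cells(800, seed = 14)
  withr::with_seed(15, {
    y <- rnbinom(800, mu = (2e-4 + 2e-4 * cells$radial_position) * cells$total_umis,
                 size = 5)
  })
  f_full <- fit_gene(y, cells)
  thin <- downsample_counts(matrix(y, 1, dimnames = list("g", cells$cell_id)),
                            0.3, seed = 16)
  cells_thin <- dplyr::mutate(cells, total_umis = pmax(1, round(total_umis * 0.3)))
  f_thin <- fit_gene(thin[1, ], cells_thin)
  for (r in c(0, 0.5, 1)) {
    full <- sum(f_full$coef * c(1, r, r^2))
    th <- sum(f_thin$coef * c(1, r, r^2))
    se <- sqrt(sum((f_full$se[1:3] * c(1, r, r^2))^2) +
                 sum((f_thin$se[1:3] * c(1, r, r^2))^2))
    expect_lt(abs(full - th), 4 * se)
  }
})
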