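test_that("bandwidth selection is scale equivariant and translation invariant", {
  set.seed(51)
  x <- rnorm(200)
  bw <- sj_bandwidth(x)
  expect_gt(bw, 0)
  # equivariance holds to the accuracy of the plug-in equation's root search
  expect_equal(sj_bandwidth(3.7 * x), 3.7 * bw, tolerance = 1e-3)
  expect_equal(sj_bandwidth(x + 11), bw, tolerance = 1e-3)
  expect_error(sj_bandwidth(rnorm(5)), "at least 10")
  # degenerate spread (plug-in equation has no solution) falls back to
  # Silverman with a warning
  expect_warning(bw0 <- sj_bandwidth(c(rep(1, 49), 2)), "Silverman")
  expect_gt(bw0, 0)
})

test_that("gene sampling covers the abundance range evenly where genes exist", {
  set.seed(52)
  lg <- c(rnorm(400, -1.2, 0.45), rnorm(400, 0.4, 0.45))
  gm <- setNames(10^lg, sprintf("g%03d", 1:800))

  # asking for every gene returns every gene, any seed
  expect_setequal(sample_estimation_genes(gm, 800, seed = 9), names(gm))
  expect_setequal(sample_estimation_genes(gm, 5000, seed = 10), names(gm))
  # deterministic given the seed
  expect_identical(sample_estimation_genes(gm, 200, seed = 7),
                   sample_estimation_genes(gm, 200, seed = 7))
  expect_error(sample_estimation_genes(gm, 0), "positive")

  br <- seq(min(lg), max(lg), length.out = 11)
  sel <- unlist(lapply(1:500, function(s)
    sample_estimation_genes(gm, 200, seed = s)))
  p_sel <- hist(log10(gm[sel]), breaks = br, plot = FALSE)$counts
  p_sel <- p_sel / sum(p_sel)
  p_gene <- hist(lg, breaks = br, plot = FALSE)$counts / 800

  # inverse-density weighting flattens the selection histogram relative to
  # the gene histogram
  expect_lt(max(p_sel[p_sel > 0]) / min(p_sel[p_sel > 0]),
            max(p_gene[p_gene > 0]) / min(p_gene[p_gene > 0]))
  # inner bins (where gene supply exceeds the uniform share) are uniform at
  # the scale of a single 200-gene draw; the outermost bins are capped by
  # gene supply and cannot reach the uniform share
  inner <- 2:9
  p_inner <- p_sel[inner] / sum(p_sel[inner])
  stat <- sum((200 * p_inner - 200 / 8)^2 / (200 / 8))
  expect_gt(pchisq(stat, df = 7, lower.tail = FALSE), 0.01)
})

test_that("kernel smoother follows the Nadaraya-Watson hand calculation", {
  # constant response: constant output
  q <- seq(-2, 2, length.out = 9)
  expect_equal(kernel_smooth(q, rnorm(20), rep(3.5, 20), bandwidth = 1),
               rep(3.5, 9))
  # convex combination: bounded by data range
  set.seed(53)
  xd <- runif(50)
  yd <- rnorm(50)
  out <- kernel_smooth(runif(20, -0.5, 1.5), xd, yd, bandwidth = 0.3)
  expect_true(all(out >= min(yd) & out <= max(yd)))

  # three-point hand calculation with the quartile scaling convention:
  # sigma = 0.25 * bandwidth / qnorm(0.75); choose bandwidth so sigma = 1
  bw <- 1 / (0.25 / qnorm(0.75))
  w <- dnorm(c(1, 0, 1))       # distances of x_data to the query at 1
  hand <- sum(w * c(0, 1, 0)) / sum(w)
  got <- kernel_smooth(1, c(0, 1, 2), c(0, 1, 0), bandwidth = bw)
  expect_equal(got, hand, tolerance = 1e-7)

  # far-outside queries fall back to the nearest evaluable estimate
  far <- kernel_smooth(c(50, -50), c(0, 1, 2), c(0, 1, 0), bandwidth = bw)
  expect_true(all(is.finite(far)))
  # query order is preserved
  ord <- kernel_smooth(c(2, 0, 1), c(0, 1, 2), c(5, 6, 7), bandwidth = bw)
  rev_ord <- kernel_smooth(c(0, 1, 2), c(0, 1, 2), c(5, 6, 7), bandwidth = bw)
  expect_equal(ord, rev_ord[c(3, 1, 2)])
})

test_that("regularize reproduces constants and interpolates all genes", {
  gm <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   gmean = 10^seq(-2, 1, length.out = 40))
  raw <- data.frame(gene_id = gm$gene_id[seq(1, 40, 2)],
                    gmean = gm$gmean[seq(1, 40, 2)],
                    beta0 = -7, beta1 = 2.3, theta = 5,
                    se_beta0 = 0.1, se_beta1 = 0.1, se_theta = 0.1,
                    method = "poisson_theta", converged = TRUE)
  reg <- regularize(raw, gm, baf = 3)
  expect_identical(nrow(reg), 40L)  # genes absent from the subset included
  expect_equal(reg$beta0, rep(-7, 40))
  expect_equal(reg$beta1, rep(2.3, 40))
  expect_equal(reg$theta, rep(5, 40), tolerance = 1e-8)
  expect_true(all(reg$theta > 0))
  bw <- attr(reg, "bandwidths")
  expect_named(bw, c("beta0", "beta1", "log10_theta", "baf"))
  expect_error(regularize(raw, gm, baf = 0), "baf")
  # determinism: identical inputs give identical outputs
  expect_identical(regularize(raw, gm, baf = 3), regularize(raw, gm, baf = 3))
})

test_that("regularized values stay within the range of the raw estimates", {
  set.seed(54)
  gm <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   gmean = 10^runif(200, -2, 1))
  raw <- data.frame(gene_id = gm$gene_id, gmean = gm$gmean,
                    beta0 = rnorm(200, -7, 1),
                    beta1 = rnorm(200, 2.3, 0.5),
                    theta = 10^rnorm(200, 0.5, 0.5),
                    se_beta0 = 0.1, se_beta1 = 0.1, se_theta = 0.1,
                    method = "poisson_theta", converged = TRUE)
  reg <- regularize(raw, gm, baf = 3)
  expect_true(all(reg$beta0 >= min(raw$beta0) & reg$beta0 <= max(raw$beta0)))
  expect_true(all(reg$beta1 >= min(raw$beta1) & reg$beta1 <= max(raw$beta1)))
  expect_true(all(reg$theta >= min(raw$theta) & reg$theta <= max(raw$theta)))
})

test_that("regularization denoises a smooth parameter trend (13 seeds)", {
  wins <- vapply(1:13, function(s) {
    set.seed(600 + s)
    n <- 2000
    lg <- runif(n, -2, 1)
    truth <- 2 + 0.4 * sin(lg * 2) + 0.2 * lg
    noisy <- truth + rnorm(n, sd = 0.3)
    gm <- data.frame(gene_id = sprintf("g%04d", 1:n), gmean = 10^lg)
    raw <- data.frame(gm, beta0 = noisy, beta1 = noisy,
                      theta = 10, se_beta0 = 0.1, se_beta1 = 0.1,
                      se_theta = 0.1, method = "poisson_theta",
                      converged = TRUE)
    reg <- regularize(raw, gm, baf = 3)
    rmse_reg <- sqrt(mean((reg$beta1 - truth)^2))
    rmse_raw <- sqrt(mean((noisy - truth)^2))
    rmse_reg < rmse_raw
  }, logical(1))
  expect_true(all(wins))
})

test_that("residual variances are robust to the bandwidth adjustment factor", {
  fit <- shared_fit()
  counts <- fit$counts
  depths <- fit$cell_attr$depth
  gs <- fit$gene_attr[, c("gene_id", "gmean")]
  base_var <- NULL
  rel_change <- sapply(c(1, 10), function(baf) {
    reg <- regularize(fit$raw_models, gs, baf = baf)
    res <- pearson_residuals(counts, reg, depths)
    v <- residual_summaries(res)$variance
    if (is.null(base_var)) base_var <<- v
    v
  })
  v3 <- fit$gene_attr$residual_variance
  for (k in 1:2) {
    expect_lt(median(abs(rel_change[, k] - v3) / v3), 0.05)
  }
})
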