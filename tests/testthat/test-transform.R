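one_gene_model <- function(beta0, beta1, theta, gene = "g1") {
  data.frame(gene_id = gene, gmean = 1, beta0 = beta0, beta1 = beta1,
             theta = theta, stringsAsFactors = FALSE)
}

counts_row <- function(x, gene = "g1") {
  m <- Matrix::Matrix(matrix(x, nrow = 1), sparse = TRUE)
  dimnames(m) <- list(gene, paste0("c", seq_along(x)))
  m
}

test_that("Pearson residuals follow the regularized-model formula", {
  # mu = exp(-ln 1000 + ln 10 * log10(2000)) = 2; sigma = sqrt(2 + 4/10)
  model <- one_gene_model(-log(1000), log(10), 10)
  res <- pearson_residuals(counts_row(c(5, 0)), model,
                           depths = c(2000, 2000), clip = "none")
  expect_equal(res["g1", "c1"], (5 - 2) / sqrt(2.4), tolerance = 1e-12)
  expect_equal(res["g1", "c1"], 1.936492, tolerance = 1e-6)
  # observation equal to its expectation has residual zero
  res0 <- pearson_residuals(counts_row(c(2, 2)), model,
                            depths = c(2000, 2000), clip = "none")
  expect_equal(unname(res0[1, ]), c(0, 0))
})

test_that("theta at the cap reduces residuals to the Poisson form", {
  model <- one_gene_model(-log(1000), log(10), theta_cap_default)
  x <- c(0, 1, 5, 9)
  m <- c(1000, 2000, 3000, 4000)
  res <- pearson_residuals(counts_row(x), model, depths = m, clip = "none")
  mu <- exp(-log(1000) + log(10) * log10(m))
  expect_equal(unname(res[1, ]), (x - mu) / sqrt(mu), tolerance = 1e-3)
})

test_that("clipping is symmetric at sqrt(N) and configurable", {
  # an extreme count: unclipped residual far above sqrt(N)
  n <- 100
  model <- one_gene_model(-log(1000), log(10), 100)
  x <- c(rep(2, n - 1), 500)
  m <- rep(2000, n)
  res <- pearson_residuals(counts_row(x), model, depths = m)
  expect_equal(attr(res, "clip_value"), sqrt(n))
  expect_equal(max(res), sqrt(n))
  expect_true(all(abs(res) <= sqrt(n)))
  # a residual of 15 at N = 100 cells is stored as 10
  unclipped <- pearson_residuals(counts_row(x), model, depths = m,
                                 clip = "none")
  stopifnot(max(unclipped) > 15)
  expect_equal(max(res), 10)
  # custom clip value
  res2 <- pearson_residuals(counts_row(x), model, depths = m,
                            clip = "custom", clip_value = 3)
  expect_equal(max(abs(res2)), 3)
  expect_error(pearson_residuals(counts_row(x), model, depths = m,
                                 clip = "custom"), "clip_value")
})

test_that("invalid model parameters are reported with the gene name", {
  model <- one_gene_model(-7, 2.3, -1)
  expect_error(pearson_residuals(counts_row(c(1, 2)), model,
                                 depths = c(100, 200)), "g1")
  expect_error(pearson_residuals(counts_row(c(1, 2), gene = "other"),
                                 one_gene_model(-7, 2.3, 1),
                                 depths = c(100, 200)), "other")
})

test_that("residual summaries match two-cell hand arithmetic", {
  res <- matrix(c(1, -1, 2, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  sm <- residual_summaries(res)
  expect_equal(sm$mean, c(0, 1))
  expect_equal(sm$variance, c(2, 2))
  z <- residual_summaries(matrix(0, 1, 4, dimnames = list("g", NULL)))
  expect_equal(c(z$mean, z$variance), c(0, 0))
})

test_that("variable-gene ranking orders by variance with gmean tie-breaks", {
  res <- matrix(c(3, -3, 3, -3,
                  1, -1, 1, -1,
                  3, -3, 3, -3), nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  gmeans <- c(gA = 1, gB = 5, gC = 2)
  top <- rank_variable_genes(res, top_n = 3, gene_means = gmeans)
  # gA and gC tie on variance; gC has the larger gmean
  expect_identical(top$gene_id, c("gC", "gA", "gB"))
  # top_n = gene count is a permutation of all genes
  expect_setequal(rank_variable_genes(res, 3)$gene_id,
                  rownames(res))
  # identical variance and gmean: lexicographic
  gmeans2 <- c(gA = 1, gB = 5, gC = 1)
  expect_identical(rank_variable_genes(res, 2, gmeans2)$gene_id[1:2],
                   c("gA", "gC"))
})

test_that("residuals are uncorrelated with depth on homogeneous data", {
  fit <- acceptance_fit()
  depths <- fit$cell_attr$depth
  cors <- apply(fit$residuals, 1, stats::cor, y = depths)
  expect_lt(median(abs(cors)), 0.05)
  # contrast: log-normalized abundant genes stay depth-correlated
  ln <- as.matrix(log_normalize(fit$counts))
  abundant <- fit$gene_attr$gene_id[order(-fit$gene_attr$gmean)][1:50]
  cors_ln <- apply(ln[abundant, ], 1, stats::cor, y = depths)
  expect_gt(median(abs(cors_ln)), 0.05)
})

test_that("clipping touches under 1% of entries at default settings", {
  fit <- acceptance_fit()
  frac <- mean(abs(fit$residuals) >= fit$params$clip_value)
  expect_lt(frac, 0.01)
})

test_that("an all-zero covariate leaves the residuals unchanged", {
  fit <- shared_fit()
  res2 <- fit_with_covariates(fit$counts, fit$model,
                              data.frame(batch = rep(0, ncol(fit$counts))),
                              depths = fit$cell_attr$depth)
  expect_equal(unname(as.matrix(res2)), unname(as.matrix(fit$residuals)),
               tolerance = 1e-12)
})

test_that("a planted multiplicative batch effect is recovered as its log coefficient", {
  params <- simulate_gene_params(n_genes = 120, gmean_range = c(0.05, 20),
                                 shape = "loguniform", seed = 71)
  sim <- simulate_homogeneous(params, n_cells = 2000, seed = 72)
  counts <- sim$counts
  m <- sim$depth_drawn  # the depth covariate the counts were generated from
  batch <- rep(c(0, 1), length.out = ncol(counts))
  # multiply batch-1 means by e^0.5: regenerate those cells at shifted means
  set.seed(73)
  for (j in which(batch == 1)) {
    mu <- exp(params$beta0 + params$beta1 * log10(m[j])) * exp(0.5)
    counts[, j] <- rnbinom(nrow(counts), size = params$theta, mu = mu)
  }
  counts <- Matrix::drop0(counts)
  model <- params  # generating truth as the regularized model
  res <- fit_with_covariates(counts, model, data.frame(batch = batch),
                             depths = m)
  co <- attr(res, "covariate_coefficients")[, "batch"]
  ok <- params$gmean > 0.1
  expect_lt(median(abs(co[ok] - 0.5)), 0.1)

  # null case: no planted effect gives coefficients centered at 0
  res0 <- fit_with_covariates(sim$counts, model, data.frame(batch = batch),
                              depths = m)
  co0 <- attr(res0, "covariate_coefficients")[, "batch"]
  expect_lt(abs(median(co0[ok])), 0.05)
})

test_that("collinear covariates are rejected with the offending columns named", {
  fit <- shared_fit()
  n <- ncol(fit$counts)
  cov <- data.frame(a = rep(c(0, 1), length.out = n))
  cov$b <- cov$a * 2
  expect_error(fit_with_covariates(fit$counts[1:2, ], fit$model, cov,
                                   depths = fit$cell_attr$depth),
               "collinear")
})
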