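# Independent oracles: a hand-rolled Newton-Raphson maximizer of the
# Poisson log-likelihood, and a grid search over the NB profile likelihood
# for theta. Neither touches glm.fit / theta.ml.

newton_poisson <- function(x, m, tol = 1e-10, max_iter = 200) {
  X <- cbind(1, log10(m))
  beta <- c(log(mean(x) + 0.1), 0)
  for (it in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta))
    grad <- drop(crossprod(X, x - mu))
    hess <- -crossprod(X * mu, X)
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

grid_theta <- function(x, mu, n_grid = 1e5) {
  grid <- 10^seq(-3, 6, length.out = n_grid)
  ll <- vapply(grid,
               function(th) sum(dnbinom(x, size = th, mu = mu, log = TRUE)),
               numeric(1))
  grid[which.max(ll)]
}

test_that("Poisson coefficients are exact on log-linear counts", {
  # counts exactly proportional to depth: the ML fit interpolates
  fit <- fit_poisson_coefficients(c(1, 2, 4), c(1000, 2000, 4000))
  expect_equal(fit$beta1, log(10), tolerance = 1e-6)
  expect_equal(fit$beta0, -log(1000), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(c(fit$se_beta0, fit$se_beta1) >= 0))
})

test_that("depth rescaling shifts the intercept by -beta1*log10(c) only", {
  set.seed(21)
  m <- round(rlnorm(200, 7.5, 0.35))
  x <- rpois(200, 0.002 * m)
  f1 <- fit_poisson_coefficients(x, m)
  f2 <- fit_poisson_coefficients(x, m * 50)
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-6)
  expect_equal(f2$beta0, f1$beta0 - f1$beta1 * log10(50), tolerance = 1e-6)
})

test_that("Poisson fit matches the Newton-Raphson oracle", {
  x <- c(0, 1, 3, 2, 8)
  m <- c(500, 800, 1200, 2000, 5000)
  fit <- fit_poisson_coefficients(x, m)
  oracle <- newton_poisson(x, m)
  expect_equal(fit$beta0, oracle[1], tolerance = 1e-6)
  expect_equal(fit$beta1, oracle[2], tolerance = 1e-6)
})

test_that("degenerate gene inputs are rejected", {
  expect_error(fit_poisson_coefficients(c(0, 0, 0), c(1, 2, 3)), "all-zero")
  expect_error(fit_poisson_coefficients(c(1, 2, 3), c(100, 100, 100)),
               "singular")
  expect_error(fit_poisson_coefficients(c(1, 2), c(100, 200, 300)), "length")
})

test_that("theta ML matches a 1e5-point grid search and is permutation invariant", {
  x <- c(0, 0, 1, 2, 10, 3)
  mu <- rep(2.5, 6)
  est <- estimate_theta_ml(x, 2.5)  # scalar mu recycled
  oracle <- grid_theta(x, mu)
  expect_equal(est$theta, oracle, tolerance = 5e-3)
  expect_gt(est$se_theta, 0)
  # joint permutation of (x, mu) leaves theta unchanged
  set.seed(31)
  mu2 <- runif(6, 1, 4)
  perm <- sample(6)
  e1 <- estimate_theta_ml(x, mu2)
  e2 <- estimate_theta_ml(x[perm], mu2[perm])
  expect_equal(e1$theta, e2$theta, tolerance = 1e-8)
})

test_that("underdispersed data drive theta to the cap with a boundary flag", {
  x <- rep(3, 50)  # zero variance at mu = 3
  est <- estimate_theta_ml(x, 3)
  expect_identical(est$theta, theta_cap_default)
  expect_false(est$converged)
})

test_that("alternating NB fit agrees with Poisson in the large-theta regime", {
  set.seed(41)
  m <- round(rlnorm(2000, 7.5, 0.35))
  x <- rpois(2000, exp(-6.9 + log(10) * log10(m)))
  nb <- fit_nb_alternating(x, m)
  po <- fit_poisson_coefficients(x, m)
  expect_equal(nb$beta0, po$beta0, tolerance = 1e-4)
  expect_equal(nb$beta1, po$beta1, tolerance = 1e-4)
  expect_gt(nb$theta, 100)
})

test_that("alternating NB fit recovers planted theta (13 seeds, 2000 cells)", {
  rel_err <- vapply(1:13, function(s) {
    set.seed(400 + s)
    m <- round(rlnorm(2000, 7.5, 0.35))
    mu <- exp(log(2) + log(10) * (log10(m) - 7.5 * log10(exp(1))))
    x <- rnbinom(2000, size = 2, mu = mu)
    fit <- fit_nb_alternating(x, m)
    abs(fit$theta - 2) / 2
  }, numeric(1))
  expect_lt(median(rel_err), 0.2)
})

test_that("initializing at the optimum returns the same values", {
  set.seed(43)
  m <- round(rlnorm(500, 7.5, 0.35))
  x <- rnbinom(500, size = 3, mu = 0.002 * m)
  fit <- fit_nb_alternating(x, m)
  again <- fit_nb_alternating(x, m, init = list(theta = fit$theta))
  expect_equal(again$beta0, fit$beta0, tolerance = 1e-6)
  expect_equal(again$theta, fit$theta, tolerance = 1e-4)
})

test_that("method 1 composes the Poisson and theta-ML steps; table shape is right", {
  sim <- shared_sim()
  counts <- filter_genes(sim$counts, 5)
  depths <- compute_depths(counts)
  g <- rownames(counts)[5]
  tab <- fit_gene_models(counts, depths, genes = g)
  expect_identical(nrow(tab), 1L)
  po <- fit_poisson_coefficients(as.numeric(counts[g, ]), depths)
  th <- estimate_theta_ml(as.numeric(counts[g, ]), po$mu)
  expect_equal(tab$beta0, po$beta0)
  expect_equal(tab$beta1, po$beta1)
  expect_equal(tab$theta, th$theta)
  expect_match(tab$method, "poisson_theta")
})

test_that("alternating likelihood dominates method 1 per gene", {
  sim <- shared_sim()
  counts <- filter_genes(sim$counts, 5)
  depths <- compute_depths(counts)
  genes <- rownames(counts)[seq(10, 200, by = 10)]
  t1 <- fit_gene_models(counts, depths, method = "poisson_theta",
                        genes = genes)
  t3 <- fit_gene_models(counts, depths, method = "nb_alternating",
                        genes = genes)
  shared <- intersect(t1$gene_id, t3$gene_id)
  for (g in shared) {
    x <- as.numeric(counts[g, ])
    r1 <- t1[t1$gene_id == g, ]
    r3 <- t3[t3$gene_id == g, ]
    ll1 <- nb_loglik(x, depths, r1$beta0, r1$beta1, r1$theta)
    ll3 <- nb_loglik(x, depths, r3$beta0, r3$beta1, r3$theta)
    # slack at the alternating iteration's convergence tolerance
    expect_gte(ll3, ll1 - 1e-3)
  }
})

test_that("NB fitted means converge to Poisson means as theta reaches the cap", {
  set.seed(45)
  m <- round(rlnorm(300, 7.5, 0.35))
  x <- rpois(300, 0.003 * m)
  X <- cbind(1, log10(m))
  po <- fit_poisson_coefficients(x, m)
  nb <- nbvst:::fit_nb_fixed_theta(x, X, theta = theta_cap_default)
  expect_equal(nb$mu, po$mu, tolerance = 1e-3)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  se_at <- function(n, seed) {
    set.seed(seed)
    m <- round(rlnorm(n, 7.5, 0.35))
    x <- rnbinom(n, size = 2, mu = 0.002 * m)
    fit_poisson_coefficients(x, m)$se_beta1
  }
  ses <- sapply(c(200, 800, 3200), function(n) {
    median(sapply(1:5, function(s) se_at(n, 1000 * n + s)))
  })
  # quadrupling n should halve the SE (within 25% slack)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})
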