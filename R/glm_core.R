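# Per-gene GLMs of UMI counts on log10 depth.
#
# The model for gene i is  log(E(x_i)) = beta0 + beta1 * log10(m),
# with natural-log link but log10 depth covariate, so beta1 has units
# "per decade of sequencing depth". NB variance is mu + mu^2/theta.

#' Cap applied to the NB dispersion estimate
#'
#' Maximum-likelihood theta diverges for underdispersed genes (the NB
#' likelihood is increasing in theta whenever the sample variance does not
#' exceed the mean). Estimates are capped at \code{1e6}, which is
#' numerically indistinguishable from Poisson at single-cell count
#' magnitudes.
#' @export
theta_cap_default <- 1e6

#' Fit Poisson regression coefficients for one gene
#'
#' Maximum-likelihood \code{(beta0, beta1)} for
#' \code{log mu_j = beta0 + beta1 * log10(m_j)} under Poisson error, via
#' iteratively reweighted least squares. Standard errors come from the
#' Fisher information at the optimum.
#'
#' @param x UMI counts of one gene across cells.
#' @param m Per-cell depths (total UMI, all > 0).
#' @return List with \code{beta0}, \code{beta1}, \code{se_beta0},
#'   \code{se_beta1}, \code{mu} (fitted means), \code{converged}.
#' @export
fit_poisson_coefficients <- function(x, m) {
  check_gene_input(x, m)
  X <- cbind(`(Intercept)` = 1, log10_m = log10(m))
  fit <- suppressWarnings(
    stats::glm.fit(X, x, family = stats::poisson(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  se <- coef_se(X, fit$weights)
  list(beta0 = unname(fit$coefficients[1]),
       beta1 = unname(fit$coefficients[2]),
       se_beta0 = se[1], se_beta1 = se[2],
       mu = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

check_gene_input <- function(x, m) {
  if (length(x) != length(m)) stop("x and m differ in length")
  if (any(m <= 0)) stop("all depths must be positive")
  if (all(x == 0)) stop("all-zero gene; filter genes before fitting")
  if (length(unique(m)) < 2L) {
    stop("no variation in depth: design is singular")
  }
  invisible(TRUE)
}

# SE of IRLS coefficients from the weighted design (Fisher information).
coef_se <- function(X, w) {
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, ncol(X)))
  sqrt(pmax(diag(cov), 0))
}

#' Maximum-likelihood NB dispersion with fixed means
#'
#' Estimates theta of the NB distribution with variance
#' \code{mu + mu^2/theta}, holding the per-cell means fixed. Uses the
#' scoring iteration of \code{MASS::theta.ml} (observed-information SE);
#' on failure falls back to Brent optimization of the profile
#' log-likelihood over log(theta). Estimates at or above \code{theta_cap}
#' are capped and flagged as boundary fits.
#'
#' @param x UMI counts of one gene.
#' @param mu Fitted mean for each cell (all > 0); a scalar is recycled.
#' @param theta_cap Upper bound for theta.
#' @return List with \code{theta}, \code{se_theta}, \code{converged}
#'   (\code{FALSE} when capped at the boundary).
#' @export
estimate_theta_ml <- function(x, mu, theta_cap = theta_cap_default) {
  if (length(mu) == 1L) mu <- rep(mu, length(x))
  if (length(x) != length(mu)) stop("x and mu differ in length")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be finite and > 0")

  # no excess variance over Poisson: the likelihood increases in theta
  # without bound, so the estimate sits at the cap (boundary fit)
  if (sum((x - mu)^2 - mu) <= 0) {
    return(list(theta = theta_cap, se_theta = NA_real_, converged = FALSE))
  }

  th <- tryCatch({
    est <- suppressWarnings(MASS::theta.ml(x, mu, limit = 100))
    list(theta = as.numeric(est), se = as.numeric(attr(est, "SE")),
         ok = TRUE)
  }, error = function(e) NULL)

  if (is.null(th) || !is.finite(th$theta) || th$theta <= 0) {
    # profile likelihood on log(theta); bounded, derivative-free
    ll <- function(lt) sum(stats::dnbinom(x, size = exp(lt), mu = mu,
                                          log = TRUE))
    opt <- stats::optimize(ll, interval = c(log(1e-4), log(theta_cap)),
                           maximum = TRUE, tol = 1e-8)
    th <- list(theta = exp(opt$maximum), se = NA_real_, ok = TRUE)
    # observed information of the profile likelihood by central difference
    h <- 1e-4
    d2 <- (ll(opt$maximum + h) - 2 * opt$objective + ll(opt$maximum - h)) / h^2
    if (is.finite(d2) && d2 < 0) {
      # delta method: Var(theta) = Var(log theta) * theta^2
      th$se <- sqrt(-1 / d2) * th$theta
    }
  }

  if (th$theta >= 0.99 * theta_cap) {
    return(list(theta = theta_cap, se_theta = NA_real_, converged = FALSE))
  }
  list(theta = th$theta,
       se_theta = if (is.finite(th$se)) th$se else NA_real_,
       converged = th$ok)
}

#' Fit one gene by alternating NB iteration
#'
#' Jointly estimates \code{(beta0, beta1, theta)} by alternating IRLS for
#' the coefficients given theta with ML for theta given the fitted means,
#' as implemented by \code{MASS::glm.nb}. This is the most expensive of the
#' three per-gene estimation methods and the reference the cheaper ones are
#' checked against.
#'
#' @param x,m As in \code{\link{fit_poisson_coefficients}}.
#' @param init Optional list with \code{theta} used as the starting value.
#' @param theta_cap Upper bound for theta.
#' @return List with \code{beta0}, \code{beta1}, \code{theta}, the three
#'   standard errors, \code{mu}, \code{method = "nb_alternating"},
#'   \code{converged}.
#' @export
fit_nb_alternating <- function(x, m, init = NULL,
                               theta_cap = theta_cap_default) {
  check_gene_input(x, m)
  log10_m <- log10(m)
  df <- data.frame(x = x, log10_m = log10_m)
  fit <- tryCatch({
    if (!is.null(init) && is.finite(init$theta)) {
      suppressWarnings(MASS::glm.nb(x ~ log10_m, data = df,
                                    init.theta = min(init$theta, theta_cap)))
    } else {
      suppressWarnings(MASS::glm.nb(x ~ log10_m, data = df))
    }
  }, error = function(e) NULL)

  if (is.null(fit)) {
    # degenerate likelihood surface (typically underdispersion): Poisson
    # coefficients with theta at the cap is the limit model
    po <- fit_poisson_coefficients(x, m)
    return(list(beta0 = po$beta0, beta1 = po$beta1, theta = theta_cap,
                se_beta0 = po$se_beta0, se_beta1 = po$se_beta1,
                se_theta = NA_real_, mu = po$mu,
                method = "nb_alternating", converged = FALSE))
  }

  theta <- min(fit$theta, theta_cap)
  sm <- summary(fit)
  list(beta0 = unname(fit$coefficients[1]),
       beta1 = unname(fit$coefficients[2]),
       theta = theta,
       se_beta0 = sm$coefficients[1, 2],
       se_beta1 = sm$coefficients[2, 2],
       se_theta = if (is.null(fit$SE.theta)) NA_real_ else fit$SE.theta,
       mu = fit$fitted.values,
       method = "nb_alternating",
       converged = isTRUE(fit$converged) && fit$theta < theta_cap)
}

# Refit beta with NB error and fixed theta (method 2's second stage, and the
# per-gene engine of the covariate extension).
fit_nb_fixed_theta <- function(x, X, theta, offset = NULL) {
  fam <- MASS::negative.binomial(theta = theta)
  fit <- suppressWarnings(
    stats::glm.fit(X, x, family = fam, offset = offset,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  list(coefficients = fit$coefficients,
       se = coef_se(X, fit$weights),
       mu = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

fit_one_gene <- function(x, m, method, theta_cap) {
  if (method == "nb_alternating") {
    return(fit_nb_alternating(x, m, theta_cap = theta_cap))
  }
  po <- fit_poisson_coefficients(x, m)
  th <- estimate_theta_ml(x, po$mu, theta_cap = theta_cap)
  res <- list(beta0 = po$beta0, beta1 = po$beta1, theta = th$theta,
              se_beta0 = po$se_beta0, se_beta1 = po$se_beta1,
              se_theta = th$se_theta, mu = po$mu, method = method,
              converged = po$converged && th$converged)
  if (method == "poisson_theta_refit") {
    X <- cbind(1, log10(m))
    re <- fit_nb_fixed_theta(x, X, th$theta)
    res$beta0 <- unname(re$coefficients[1])
    res$beta1 <- unname(re$coefficients[2])
    res$se_beta0 <- re$se[1]
    res$se_beta1 <- re$se[2]
    res$mu <- re$mu
    res$converged <- res$converged && re$converged
  }
  res
}

#' Fit per-gene GLMs for a set of genes
#'
#' Dispatches each gene to one of three estimation methods, in increasing
#' order of cost:
#' \describe{
#'   \item{\code{poisson_theta}}{Poisson IRLS for the coefficients, then ML
#'     for theta with the Poisson means fixed (default).}
#'   \item{\code{poisson_theta_refit}}{As above, then an NB re-fit of the
#'     coefficients with the estimated theta held fixed.}
#'   \item{\code{nb_alternating}}{Full alternating NB iteration.}
#' }
#' The resulting Pearson residuals are nearly identical across methods;
#' the cheap default exists because these raw fits only feed the
#' cross-gene regularization step.
#'
#' @param counts Gene x cell count matrix (filtered).
#' @param depths Per-cell depths; recomputed when missing.
#' @param method Estimation method, see above.
#' @param genes Optional character vector restricting the genes fitted.
#' @param eps Pseudo-offset for the geometric gene mean.
#' @param theta_cap Upper bound for theta.
#' @param verbose Log per-gene failures to stderr.
#' @return \code{data.frame} with one row per successfully fitted gene:
#'   \code{gene_id}, \code{gmean}, \code{beta0}, \code{beta1}, \code{theta},
#'   \code{se_beta0}, \code{se_beta1}, \code{se_theta}, \code{method},
#'   \code{converged}.
#' @export
fit_gene_models <- function(counts,
                            depths = NULL,
                            method = c("poisson_theta", "poisson_theta_refit",
                                       "nb_alternating"),
                            genes = NULL,
                            eps = 1,
                            theta_cap = theta_cap_default,
                            verbose = FALSE) {
  method <- match.arg(method)
  counts <- validate_counts(counts)
  if (is.null(depths)) depths <- Matrix::colSums(counts)
  if (any(depths <= 0)) stop("remove zero-depth cells before fitting")
  gs <- gene_summary(counts, eps = eps)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing)) {
      stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "))
    }
  } else {
    genes <- rownames(counts)
  }
  gmean <- stats::setNames(gs$gmean, gs$gene_id)

  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    x <- as.numeric(counts[g, ])
    fit <- tryCatch(fit_one_gene(x, depths, method, theta_cap),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (verbose) message("gene ", g, " dropped: ", conditionMessage(fit))
      next
    }
    rows[[k]] <- data.frame(
      gene_id = g, gmean = unname(gmean[g]),
      beta0 = fit$beta0, beta1 = fit$beta1, theta = fit$theta,
      se_beta0 = fit$se_beta0, se_beta1 = fit$se_beta1,
      se_theta = fit$se_theta,
      method = method, converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) stop("no gene could be fitted")
  rownames(out) <- NULL
  out
}

#' NB log-likelihood of a gene model
#'
#' Log-likelihood of counts under the depth model
#' \code{mu_j = exp(beta0 + beta1 log10 m_j)} with dispersion theta; used in
#' tests to verify optimality of the alternating fit.
#'
#' @param x,m Counts and depths.
#' @param beta0,beta1,theta Model parameters.
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(x, m, beta0, beta1, theta) {
  mu <- exp(beta0 + beta1 * log10(m))
  sum(stats::dnbinom(x, size = theta, mu = mu, log = TRUE))
}
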