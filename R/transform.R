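# Pearson residuals under the regularized model, per-gene residual
# summaries, variable-gene ranking, and the second-round regression for
# nuisance covariates.

#' Pearson residuals of the regularized NB model
#'
#' Transforms counts into normalized values
#' \deqn{z_{ij} = (x_{ij} - \mu_{ij}) / \sigma_{ij}}
#' with \eqn{\mu_{ij} = \exp(\beta_{0i} + \beta_{1i} \log_{10} m_j)} and
#' \eqn{\sigma_{ij} = \sqrt{\mu_{ij} + \mu_{ij}^2/\theta_i}} read from the
#' regularized model. To limit the leverage of extreme outliers, residuals
#' are clipped symmetrically to \code{sqrt(N)} (N = number of cells) by
#' default; negative residuals are already bounded near \eqn{-\mu/\sigma}
#' by construction, so the symmetric clip mainly guards extreme
#' high-depth cells.
#'
#' @param counts Gene x cell count matrix; every gene must appear in
#'   \code{model}.
#' @param model Regularized model table from \code{\link{regularize}} (or a
#'   raw table with the same columns).
#' @param depths Per-cell depths consistent with \code{counts}; recomputed
#'   when missing.
#' @param clip \code{"sqrt_n"} (default), \code{"none"}, or
#'   \code{"custom"} with \code{clip_value}.
#' @param clip_value Positive clip bound used when \code{clip = "custom"}.
#' @param block_size Number of genes transformed per chunk (memory control).
#' @return Dense gene x cell matrix of residuals with attributes
#'   \code{clip_value}.
#' @export
pearson_residuals <- function(counts, model, depths = NULL,
                              clip = c("sqrt_n", "none", "custom"),
                              clip_value = NULL,
                              block_size = 2000L) {
  clip <- match.arg(clip)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(depths)) depths <- Matrix::colSums(counts)
  if (length(depths) != ncol(counts)) stop("depths do not match cells")
  if (any(depths <= 0)) stop("cells with zero depth cannot be transformed")

  idx <- match(rownames(counts), model$gene_id)
  if (anyNA(idx)) {
    stop("no regularized parameters for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  }
  beta0 <- model$beta0[idx]
  beta1 <- model$beta1[idx]
  theta <- model$theta[idx]
  bad <- !is.finite(beta0) | !is.finite(beta1) | !is.finite(theta) | theta <= 0
  if (any(bad)) {
    stop("non-finite or non-positive model parameters for gene(s): ",
         paste(utils::head(rownames(counts)[bad], 5), collapse = ", "))
  }

  n <- ncol(counts)
  cv <- switch(clip,
               sqrt_n = sqrt(n),
               none = Inf,
               custom = {
                 if (is.null(clip_value) || clip_value <= 0) {
                   stop("clip = \"custom\" needs a positive clip_value")
                 }
                 clip_value
               })

  log10_m <- log10(depths)
  res <- matrix(0, nrow = nrow(counts), ncol = n,
                dimnames = dimnames(counts))
  starts <- seq(1L, nrow(counts), by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, nrow(counts))
    i <- s:e
    mu <- exp(outer(beta1[i], log10_m) + beta0[i])
    sd <- sqrt(mu + mu^2 / theta[i])
    z <- (as.matrix(counts[i, , drop = FALSE]) - mu) / sd
    res[i, ] <- pmin(pmax(z, -cv), cv)
  }
  attr(res, "clip_value") <- cv
  res
}

#' Per-gene residual mean and variance
#'
#' For a well-calibrated model on biologically homogeneous data the
#' residual means center at 0 and the residual variances peak at 1;
#' departures flag genes whose variation exceeds the technical model.
#'
#' @param res Residual matrix (genes x cells).
#' @return \code{data.frame} with \code{gene_id}, \code{mean},
#'   \code{variance} (unbiased, across cells).
#' @export
residual_summaries <- function(res) {
  if (length(res) == 0L) stop("empty residual matrix")
  mu <- rowMeans(res)
  n <- ncol(res)
  v <- if (n > 1) rowSums((res - mu)^2) / (n - 1) else rep(NA_real_, nrow(res))
  data.frame(gene_id = rownames(res), mean = unname(mu),
             variance = unname(v), stringsAsFactors = FALSE)
}

#' Rank genes by residual variance
#'
#' The residual variance under the regularized model is a direct measure of
#' biological variation not explained by sequencing depth, and ranks
#' highly variable genes. Ties are broken by geometric mean (descending),
#' then gene identifier.
#'
#' @param res Residual matrix.
#' @param top_n Number of genes to return.
#' @param gene_means Optional named vector or \code{gene_summary} table used
#'   for tie-breaking; zero for genes not listed.
#' @return \code{data.frame} of the top genes with their residual variance,
#'   ordered.
#' @export
rank_variable_genes <- function(res, top_n = 3000, gene_means = NULL) {
  if (top_n < 1) stop("top_n must be >= 1")
  sm <- residual_summaries(res)
  gm <- rep(0, nrow(sm))
  if (!is.null(gene_means)) {
    if (is.data.frame(gene_means)) {
      gene_means <- stats::setNames(gene_means$gmean, gene_means$gene_id)
    }
    hit <- match(sm$gene_id, names(gene_means))
    gm[!is.na(hit)] <- gene_means[hit[!is.na(hit)]]
  }
  ord <- order(-sm$variance, -gm, sm$gene_id)
  out <- sm[ord, c("gene_id", "variance")]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Second-round regression with nuisance covariates
#'
#' Extends the model with additional per-cell covariates (batch, cell-cycle
#' scores, mitochondrial fraction, ...). Because genes of similar abundance
#' cannot be assumed to respond similarly to such covariates, their
#' coefficients cannot be regularized; instead the depth-dependent part
#' \eqn{\beta_{0i} + \beta_{1i}\log_{10} m_j} is fixed at its regularized
#' value and enters as an offset, theta is fixed at its regularized value,
#' and only the covariate coefficients are free in a per-gene NB
#' regression. The Pearson residuals of this second round (clipped as
#' usual) are the normalized values.
#'
#' @param counts Gene x cell count matrix.
#' @param model Regularized model table.
#' @param covariates \code{data.frame} of per-cell covariates (numeric or
#'   factor; factors expand to treatment-coded indicators).
#' @param depths Per-cell depths; recomputed when missing.
#' @param clip,clip_value As in \code{\link{pearson_residuals}}.
#' @return Dense residual matrix with the fitted covariate coefficients in
#'   attribute \code{"covariate_coefficients"} (genes x coefficients).
#' @export
fit_with_covariates <- function(counts, model, covariates, depths = NULL,
                                clip = c("sqrt_n", "none", "custom"),
                                clip_value = NULL) {
  clip <- match.arg(clip)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(depths)) depths <- Matrix::colSums(counts)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(counts)) {
    stop("covariates (", nrow(covariates), " rows) do not align with ",
         ncol(counts), " cells")
  }
  # drop the intercept: it lives in the regularized beta0 of the offset
  XC <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  null_col <- apply(XC, 2, function(v) all(v == 0))
  if (any(null_col)) {
    XC <- XC[, !null_col, drop = FALSE]
  }
  if (ncol(XC) == 0L) {
    # no informative covariate: the model is the pure depth model
    return(pearson_residuals(counts, model, depths = depths, clip = clip,
                             clip_value = clip_value))
  }
  qrX <- qr(XC)
  if (qrX$rank < ncol(XC)) {
    drop_cols <- colnames(XC)[setdiff(seq_len(ncol(XC)),
                                      qrX$pivot[seq_len(qrX$rank)])]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }

  idx <- match(rownames(counts), model$gene_id)
  if (anyNA(idx)) {
    stop("no regularized parameters for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  }
  log10_m <- log10(depths)
  n <- ncol(counts)
  cv <- switch(clip, sqrt_n = sqrt(n), none = Inf, custom = clip_value)
  if (!is.finite(cv) && clip == "custom") stop("invalid clip_value")

  res <- matrix(0, nrow = nrow(counts), ncol = n, dimnames = dimnames(counts))
  coefs <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(XC),
                  dimnames = list(rownames(counts), colnames(XC)))
  for (k in seq_len(nrow(counts))) {
    i <- idx[k]
    off <- model$beta0[i] + model$beta1[i] * log10_m
    x <- as.numeric(counts[k, ])
    fit <- fit_nb_fixed_theta(x, XC, theta = model$theta[i], offset = off)
    coefs[k, ] <- fit$coefficients
    mu <- fit$mu
    sd <- sqrt(mu + mu^2 / model$theta[i])
    res[k, ] <- pmin(pmax((x - mu) / sd, -cv), cv)
  }
  attr(res, "clip_value") <- cv
  attr(res, "covariate_coefficients") <- coefs
  res
}
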