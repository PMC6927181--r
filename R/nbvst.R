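#' Regularized negative binomial variance-stabilizing transformation
#'
#' Fits the full normalization model to a UMI count matrix in three steps:
#' (1) independent per-gene GLMs of counts on log10 sequencing depth,
#' fitted on a density-balanced subset of genes; (2) kernel-regression
#' regularization of the intercept, slope and NB dispersion against
#' log10 geometric gene mean, evaluated for every gene; (3) conversion of
#' counts to Pearson residuals under the regularized model, clipped at
#' \code{sqrt(N)}. The residuals are variance-stabilized, depth-independent
#' normalized values; their per-gene variance ranks highly variable genes.
#'
#' @param counts Gene x cell UMI count matrix (sparse or dense, with
#'   dimnames), or a path readable by \code{\link{read_counts}}.
#' @param min_cells Keep genes detected in at least this many cells.
#' @param n_genes Size of the estimation gene subset (default 2000).
#' @param method Per-gene estimation method (see
#'   \code{\link{fit_gene_models}}).
#' @param baf Bandwidth adjustment factor for the regularization
#'   (default 3; results are robust over roughly 1-10).
#' @param smoother Regularization smoother, \code{"local_linear"} (default)
#'   or \code{"kernel"}; see \code{\link{regularize}}.
#' @param clip,clip_value Residual clipping, see
#'   \code{\link{pearson_residuals}}.
#' @param eps Pseudo-offset of the geometric mean (default 1).
#' @param theta_cap Upper bound for the NB dispersion.
#' @param covariates Optional per-cell \code{data.frame} of nuisance
#'   covariates; triggers the second-round regression of
#'   \code{\link{fit_with_covariates}}.
#' @param depths Optional per-cell sequencing depths (total UMI). By
#'   default the column sums of \code{counts}. Supply the full-library
#'   totals when \code{counts} is restricted to a gene subset: the depth
#'   covariate is a property of the cell's whole library, and the partial
#'   sum over few genes is a noisy proxy for it.
#' @param seed Integer seed governing the estimation-gene draw.
#' @param verbose Log progress to stderr.
#' @return Object of class \code{"nbvst"} with components \code{residuals}
#'   (dense matrix), \code{model} (regularized parameter table),
#'   \code{raw_models}, \code{gene_attr} (gmean, detection, residual mean
#'   and variance per gene), \code{cell_attr} (depth per cell),
#'   \code{estimation_genes}, \code{params} (the settings used) and
#'   \code{call}.
#' @examples
#' params <- simulate_gene_params(n_genes = 80, seed = 1)
#' sim <- simulate_homogeneous(params, n_cells = 300, seed = 1)
#' fit <- nbvst(sim$counts, n_genes = 80, seed = 1, verbose = FALSE)
#' fit
#' head(coef(fit))
#' @export
nbvst <- function(counts,
                  min_cells = 5,
                  n_genes = 2000,
                  method = c("poisson_theta", "poisson_theta_refit",
                             "nb_alternating"),
                  baf = 3,
                  smoother = c("local_linear", "kernel"),
                  clip = c("sqrt_n", "none", "custom"),
                  clip_value = NULL,
                  eps = 1,
                  theta_cap = theta_cap_default,
                  covariates = NULL,
                  depths = NULL,
                  seed = 42,
                  verbose = TRUE) {
  method <- match.arg(method)
  smoother <- match.arg(smoother)
  clip <- match.arg(clip)
  cl <- match.call()
  if (is.character(counts) && length(counts) == 1L) {
    counts <- read_counts(counts)
  }
  counts <- validate_counts(counts)
  if (is.null(depths)) {
    counts <- drop_empty_cells(counts)
    counts <- filter_genes(counts, min_cells = min_cells)
    depths <- Matrix::colSums(counts)
  } else {
    if (length(depths) != ncol(counts)) {
      stop("depths (", length(depths), ") do not match ", ncol(counts),
           " cells")
    }
    if (any(depths <= 0)) stop("all supplied depths must be positive")
    depths <- as.numeric(depths)
    names(depths) <- colnames(counts)
    keep <- Matrix::colSums(counts) > 0
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " cell(s) with zero observed UMI")
      counts <- counts[, keep, drop = FALSE]
      depths <- depths[keep]
    }
    counts <- filter_genes(counts, min_cells = min_cells)
  }
  say <- function(...) if (verbose) message(...)
  say("modeling ", nrow(counts), " genes across ", ncol(counts), " cells")

  gs <- gene_summary(counts, eps = eps)
  est_genes <- sample_estimation_genes(gs, n_genes = n_genes, seed = seed)
  say("fitting raw models for ", length(est_genes), " genes (", method, ")")
  raw <- fit_gene_models(counts, depths, method = method, genes = est_genes,
                         eps = eps, theta_cap = theta_cap, verbose = verbose)

  say("regularizing parameters (baf = ", baf, ", ", smoother, ")")
  model <- regularize(raw, gs, baf = baf, smoother = smoother,
                      theta_cap = theta_cap)

  modeled <- intersect(rownames(counts), model$gene_id)
  counts_m <- counts[modeled, , drop = FALSE]
  if (is.null(covariates)) {
    res <- pearson_residuals(counts_m, model, depths, clip = clip,
                             clip_value = clip_value)
  } else {
    say("second-round regression with ", ncol(as.data.frame(covariates)),
        " covariate column(s)")
    res <- fit_with_covariates(counts_m, model, covariates, depths,
                               clip = clip, clip_value = clip_value)
  }
  rs <- residual_summaries(res)

  gene_attr <- merge(gs, rs, by = "gene_id", sort = FALSE)
  gene_attr <- gene_attr[match(modeled, gene_attr$gene_id), ]
  names(gene_attr)[names(gene_attr) == "mean"] <- "residual_mean"
  names(gene_attr)[names(gene_attr) == "variance"] <- "residual_variance"
  rownames(gene_attr) <- NULL

  structure(list(residuals = res,
                 model = model,
                 raw_models = raw,
                 gene_attr = gene_attr,
                 cell_attr = data.frame(cell_id = colnames(counts),
                                        depth = unname(depths),
                                        stringsAsFactors = FALSE),
                 estimation_genes = est_genes,
                 counts = counts_m,
                 params = list(min_cells = min_cells, n_genes = n_genes,
                               method = method, baf = baf,
                               smoother = smoother, clip = clip,
                               clip_value = attr(res, "clip_value"),
                               eps = eps, theta_cap = theta_cap,
                               seed = seed,
                               bandwidths = attr(model, "bandwidths")),
                 call = cl),
            class = "nbvst")
}

#' @export
print.nbvst <- function(x, ...) {
  cat("Regularized NB variance-stabilizing transformation\n")
  cat(sprintf("  %d genes x %d cells; method %s; %d estimation genes\n",
              nrow(x$residuals), ncol(x$residuals), x$params$method,
              length(x$estimation_genes)))
  cat(sprintf("  residuals clipped at +/- %.3f\n", x$params$clip_value))
  bw <- x$params$bandwidths
  cat(sprintf("  bandwidths (x baf=%g): beta0 %.3g, beta1 %.3g, log10(theta) %.3g\n",
              bw["baf"], bw["beta0"], bw["beta1"], bw["log10_theta"]))
  invisible(x)
}

#' @export
summary.nbvst <- function(object, top_n = 10, ...) {
  rv <- object$gene_attr$residual_variance
  rm_ <- object$gene_attr$residual_mean
  cat("Regularized NB model summary\n")
  cat(sprintf("  genes: %d, cells: %d\n", nrow(object$residuals),
              ncol(object$residuals)))
  cat(sprintf("  depth: median %d, range %d-%d\n",
              as.integer(stats::median(object$cell_attr$depth)),
              as.integer(min(object$cell_attr$depth)),
              as.integer(max(object$cell_attr$depth))))
  cat(sprintf("  residual mean: median %.4f\n", stats::median(rm_)))
  cat(sprintf("  residual variance: median %.3f, mode %.3f\n",
              stats::median(rv), density_mode(rv)))
  cat("  top variable genes:\n")
  top <- rank_variable_genes(object$residuals, top_n = top_n,
                             gene_means = object$gene_attr)
  print(top, row.names = FALSE)
  invisible(object)
}

#' Mode of a distribution via kernel density
#'
#' Location of the highest peak of a Gaussian kernel density estimate;
#' used to summarize the per-gene residual-variance distribution, whose
#' mode is 1 for a calibrated model.
#'
#' @param x Numeric vector.
#' @param ... Passed to \code{stats::density}.
#' @return Scalar mode.
#' @export
density_mode <- function(x, ...) {
  d <- stats::density(x[is.finite(x)], ...)
  d$x[which.max(d$y)]
}

#' @export
coef.nbvst <- function(object, which = c("regularized", "raw"), ...) {
  which <- match.arg(which)
  tab <- if (which == "regularized") object$model else object$raw_models
  out <- as.matrix(tab[, c("beta0", "beta1", "theta")])
  rownames(out) <- tab$gene_id
  out
}

#' @export
residuals.nbvst <- function(object, ...) object$residuals

#' Model-implied means for new cells
#'
#' Evaluates \code{mu_ij = exp(beta0_i + beta1_i log10 m_j)} (type
#' \code{"mean"}) or the corresponding NB standard deviation (type
#' \code{"sd"}) at arbitrary depths.
#'
#' @param object Fitted \code{nbvst} object.
#' @param depths Per-cell depths; defaults to the training depths.
#' @param genes Gene subset; all modeled genes by default.
#' @param type \code{"mean"} or \code{"sd"}.
#' @param ... Unused.
#' @return Dense gene x cell matrix.
#' @export
predict.nbvst <- function(object, depths = NULL, genes = NULL,
                          type = c("mean", "sd"), ...) {
  type <- match.arg(type)
  if (is.null(depths)) depths <- object$cell_attr$depth
  if (any(depths <= 0)) stop("depths must be positive")
  model <- object$model
  if (!is.null(genes)) {
    model <- model[model$gene_id %in% genes, , drop = FALSE]
    if (nrow(model) == 0L) stop("no modeled gene in `genes`")
  }
  mu <- exp(outer(model$beta1, log10(depths)) + model$beta0)
  rownames(mu) <- model$gene_id
  if (type == "mean") return(mu)
  sqrt(mu + mu^2 / model$theta)
}

#' Simulate counts from a fitted model
#'
#' Draws NB counts from the regularized model at the training depths (or
#' supplied ones) — a parametric bootstrap of the technical-noise model.
#'
#' @param object Fitted \code{nbvst} object.
#' @param nsim Number of replicate matrices.
#' @param seed Integer seed.
#' @param depths Optional depths (defaults to training depths).
#' @param ... Unused.
#' @return A sparse count matrix, or a list of them when \code{nsim > 1}.
#' @export
simulate.nbvst <- function(object, nsim = 1, seed = NULL, depths = NULL, ...) {
  if (is.null(depths)) depths <- object$cell_attr$depth
  with_seed(seed, {
    reps <- lapply(seq_len(nsim), function(r) {
      draw_counts(object$model, depths)
    })
    if (nsim == 1) reps[[1]] else reps
  })
}

#' Plot parameter trends of a fitted model
#'
#' Scatter of the raw per-gene estimates of intercept, slope and
#' log10 dispersion against log10 geometric mean, with the regularized
#' curve overlaid — the standard visual check that the smoother tracks the
#' parameter trends.
#'
#' @param x Fitted \code{nbvst} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.nbvst <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  raw <- x$raw_models
  reg <- x$model[order(x$model$gmean), ]
  panels <- list(beta0 = expression(beta[0]),
                 beta1 = expression(beta[1]),
                 theta = expression(log[10](theta)))
  for (p in names(panels)) {
    yr <- raw[[p]]
    yg <- reg[[p]]
    if (p == "theta") {
      yr <- log10(yr)
      yg <- log10(yg)
    }
    graphics::plot(log10(raw$gmean), yr, pch = 16, cex = 0.4,
                   col = grDevices::grey(0.4, 0.5),
                   xlab = expression(log[10] ~ "geometric mean"),
                   ylab = panels[[p]], main = p, ...)
    graphics::lines(log10(reg$gmean), yg, col = "deeppink", lwd = 2)
  }
  invisible(x)
}
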