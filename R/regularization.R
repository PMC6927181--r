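# Cross-gene regularization: smooth trends of (beta0, beta1, theta) against
# geometric gene mean, learned on a representative gene subset and evaluated
# for every gene.

# Run expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Sheather-Jones plug-in bandwidth
#'
#' Solve-the-equation plug-in bandwidth for a normal-kernel smoother /
#' density estimate. Falls back to Silverman's rule of thumb (with a
#' warning) when the plug-in equation has no solution, e.g. for degenerate
#' spread.
#'
#' @param values Numeric vector (typically log10 gene means).
#' @return Positive scalar bandwidth.
#' @export
sj_bandwidth <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    stop("need at least 10 finite values for bandwidth selection")
  }
  tryCatch(stats::bw.SJ(values, method = "ste"),
           error = function(e) {
             warning("Sheather-Jones bandwidth failed (",
                     conditionMessage(e),
                     "); falling back to Silverman's rule")
             bw <- stats::bw.nrd0(values)
             if (!is.finite(bw) || bw <= 0) {
               stop("no usable bandwidth: values have no spread")
             }
             bw
           })
}

#' Sample genes for the initial estimation step
#'
#' Weighted sampling without replacement with per-gene weight
#' \code{1/d(log10 gmean)}, where \code{d} is a Gaussian kernel density
#' estimate over all log10 gene means. Uniform sampling would oversample
#' abundance regions dense in genes; inverse-density weights cover the
#' whole gene-mean range evenly, so the smoother sees support everywhere.
#' Densities are floored at their 1st percentile to avoid near-infinite
#' weights for extreme-abundance genes.
#'
#' @param gene_means \code{data.frame} with columns \code{gene_id},
#'   \code{gmean} (as from \code{\link{gene_summary}}), or a named numeric
#'   vector of gene means.
#' @param n_genes Number of genes to select (default 2000); capped at the
#'   number available, in which case all genes are returned.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Character vector of selected gene identifiers.
#' @export
sample_estimation_genes <- function(gene_means, n_genes = 2000, seed = NULL) {
  if (is.data.frame(gene_means)) {
    gmean <- stats::setNames(gene_means$gmean, gene_means$gene_id)
  } else {
    gmean <- gene_means
  }
  if (n_genes <= 0) stop("n_genes must be positive")
  ok <- is.finite(gmean) & gmean > 0
  gmean <- gmean[ok]
  if (n_genes >= length(gmean)) return(names(gmean))
  lg <- log10(gmean)
  bw <- tryCatch(sj_bandwidth(lg), warning = function(w) stats::bw.nrd0(lg))
  dens <- stats::density(lg, bw = bw, n = 512,
                         from = min(lg) - 3 * bw, to = max(lg) + 3 * bw)
  d_at <- stats::approx(dens$x, dens$y, xout = lg, rule = 2)$y
  d_at <- pmax(d_at, stats::quantile(d_at, 0.01))
  with_seed(seed, sample(names(gmean), n_genes, prob = 1 / d_at))
}

#' Kernel regression smoother
#'
#' Nadaraya-Watson estimate with a normal kernel, in the classical
#' convention that scales the kernel so its quartiles sit at
#' \code{+/- 0.25 * bandwidth} (Gaussian sigma = \code{0.3706506 *
#' bandwidth}); bandwidth numbers are therefore directly comparable across
#' smoothing steps. Query points falling where no data carry kernel weight
#' (far outside the data range) receive the nearest evaluable estimate.
#'
#' @param x_query Points at which to evaluate, any order.
#' @param x_data,y_data Training points.
#' @param bandwidth Positive bandwidth in the quartile convention above.
#' @return Numeric vector of estimates aligned with \code{x_query}.
#' @export
kernel_smooth <- function(x_query, x_data, y_data, bandwidth) {
  if (length(x_data) != length(y_data)) stop("x_data/y_data length mismatch")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ok <- is.finite(x_data) & is.finite(y_data)
  # evaluate at the data points too: they always carry kernel weight, so a
  # nearest evaluable estimate exists for any far-outside query
  pts <- c(x_query, x_data[ok])
  ks <- stats::ksmooth(x_data[ok], y_data[ok], kernel = "normal",
                       bandwidth = bandwidth, x.points = pts)
  # ksmooth sorts the evaluation points; map back to the caller's order
  y_all <- numeric(length(pts))
  y_all[order(pts)] <- ks$y
  y <- y_all[seq_along(x_query)]
  if (anyNA(y)) {
    good_x <- pts[!is.na(y_all)]
    good_y <- y_all[!is.na(y_all)]
    for (j in which(is.na(y))) {
      y[j] <- good_y[which.min(abs(good_x - x_query[j]))]
    }
  }
  y
}

#' Local-linear kernel regression
#'
#' Weighted straight-line fit at every query point with Gaussian kernel
#' weights, in the same quartile bandwidth convention as
#' \code{\link{kernel_smooth}}. Unlike the constant-fit (Nadaraya-Watson)
#' smoother it is unbiased to first order at the boundaries of the data
#' range and under uneven designs, which matters when only a few hundred
#' genes span the abundance axis. Queries with a degenerate weighted
#' design fall back to the constant fit; queries with no kernel weight to
#' the nearest data point.
#'
#' @inheritParams kernel_smooth
#' @return Numeric vector of estimates aligned with \code{x_query}.
#' @export
local_linear_smooth <- function(x_query, x_data, y_data, bandwidth) {
  if (length(x_data) != length(y_data)) stop("x_data/y_data length mismatch")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ok <- is.finite(x_data) & is.finite(y_data)
  xd <- x_data[ok]
  yd <- y_data[ok]
  sk <- 0.25 * bandwidth / stats::qnorm(0.75)
  vapply(x_query, function(x0) {
    w <- stats::dnorm((xd - x0) / sk)
    sw <- sum(w)
    if (sw < 1e-300) return(yd[which.min(abs(xd - x0))])
    z <- xd - x0
    swz <- sum(w * z)
    swzz <- sum(w * z * z)
    den <- sw * swzz - swz^2
    if (!is.finite(den) || den <= 1e-10 * sw * max(swzz, 1e-300)) {
      return(sum(w * yd) / sw)
    }
    (swzz * sum(w * yd) - swz * sum(w * z * yd)) / den
  }, numeric(1))
}

#' Regularize per-gene model parameters across genes
#'
#' Raw per-gene estimates of intercept, slope and dispersion are noisy —
#' badly so for low-abundance genes, whose apparent variance reflects
#' cell-type heterogeneity rather than a stable gene-level property.
#' Parameters are therefore replaced by kernel-regression estimates as a
#' function of log10 geometric gene mean, pooling information across genes
#' of similar abundance. Intercept and slope are smoothed on their natural
#' scale; theta is smoothed as log10(theta) and exponentiated, which
#' guarantees positivity and tames its heavy right tail. Each parameter
#' gets its own Sheather-Jones bandwidth, multiplied by the bandwidth
#' adjustment factor \code{baf} (default 3).
#'
#' Genes with failed or boundary raw fits are excluded from the smoother's
#' input but still receive regularized values at their gene mean; genes
#' beyond the abundance range of the fitted subset receive the nearest
#' estimate.
#'
#' Two smoothers are available. The default, \code{"local_linear"}
#' (\code{\link{local_linear_smooth}}), fits a kernel-weighted line at
#' every gene mean: it tracks the strong linear trend of the intercept
#' without the boundary and design bias that a constant-fit kernel
#' average incurs when only a few hundred genes span the abundance axis.
#' \code{"kernel"} is the classical Nadaraya-Watson estimate
#' (\code{\link{kernel_smooth}}); the two agree closely away from the
#' abundance extremes. Either way the regularized values are kept within
#' the range of the raw estimates entering the smoother.
#'
#' @param raw \code{data.frame} of raw fits from
#'   \code{\link{fit_gene_models}}.
#' @param gene_means \code{data.frame} with \code{gene_id}, \code{gmean} for
#'   every gene that should receive regularized parameters (typically all
#'   filtered genes, a superset of the fitted ones).
#' @param baf Bandwidth adjustment factor (> 0).
#' @param smoother \code{"local_linear"} (default) or \code{"kernel"}.
#' @param theta_cap Cap for the regularized dispersion.
#' @return \code{data.frame} with columns \code{gene_id}, \code{gmean},
#'   \code{beta0}, \code{beta1}, \code{theta}; the bandwidths used are
#'   attached as attribute \code{"bandwidths"}.
#' @export
regularize <- function(raw, gene_means, baf = 3,
                       smoother = c("local_linear", "kernel"),
                       theta_cap = theta_cap_default) {
  smoother <- match.arg(smoother)
  if (baf <= 0) stop("baf must be positive")
  if (nrow(raw) == 0L) stop("empty raw model table")
  use <- raw[is.finite(raw$beta0) & is.finite(raw$beta1) &
               is.finite(raw$theta) & raw$gmean > 0, , drop = FALSE]
  if (nrow(use) == 0L) stop("no usable raw fits to regularize")
  x_fit <- log10(use$gmean)
  keep <- gene_means$gmean > 0
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with zero gmean receive no model")
  }
  targets <- gene_means[keep, , drop = FALSE]
  x_all <- log10(targets$gmean)

  smooth_fun <- if (smoother == "local_linear") {
    local_linear_smooth
  } else {
    kernel_smooth
  }
  smooth_one_at <- function(y, x) {
    bw <- if (length(unique(x)) > 1 && stats::sd(x) > 0) {
      tryCatch(sj_bandwidth(x),
               warning = function(w) stats::bw.nrd0(x),
               error = function(e) stats::bw.nrd0(x))
    } else {
      1
    }
    # clamp to the raw range: regularized parameters are summaries of the
    # raw estimates, never extrapolations beyond them
    yy <- pmin(pmax(smooth_fun(x_all, x, y, bandwidth = bw * baf),
                    min(y)), max(y))
    list(y = yy, bw = bw)
  }
  smooth_one <- function(y) smooth_one_at(y, x_fit)

  s_b0 <- smooth_one(use$beta0)
  s_b1 <- smooth_one(use$beta1)
  # dispersion estimates at the cap are boundary fits, not ML estimates:
  # they would drag the log-scale smoother far upward wherever genes carry
  # little dispersion information (their beta fits remain usable above)
  free <- use$theta < 0.99 * theta_cap
  if (sum(free) < 2L) {
    warning("nearly all dispersion fits at the boundary; ",
            "smoothing theta over all of them")
    free <- rep(TRUE, nrow(use))
  }
  s_th <- smooth_one_at(log10(use$theta[free]), x_fit[free])

  out <- data.frame(gene_id = targets$gene_id,
                    gmean = targets$gmean,
                    beta0 = s_b0$y,
                    beta1 = s_b1$y,
                    theta = pmin(10^s_th$y, theta_cap),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "bandwidths") <- c(beta0 = s_b0$bw, beta1 = s_b1$bw,
                               log10_theta = s_th$bw, baf = baf)
  out
}
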