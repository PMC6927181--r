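# Parameter-stability diagnostics (bootstrap uncertainty scores, Wald CIs)
# and the depth-trend / variance-contribution analyses used to judge
# whether normalized values still carry sequencing-depth structure.

#' Bootstrap uncertainty of model parameters
#'
#' Resamples cells with replacement \code{n_boot} times (depths travel with
#' the sampled cells) and refits the raw per-gene models each time;
#' optionally also re-runs the regularization within each bootstrap. For a
#' gene/parameter pair the uncertainty score is the standard deviation of
#' the estimates across bootstraps divided by the standard deviation of the
#' bootstrap-mean values across all genes — scores near or above 1 flag
#' estimates dominated by sampling noise, scores at or below 0.01 flag very
#' stable ones.
#'
#' @param counts Gene x cell count matrix (filtered).
#' @param depths Per-cell depths; recomputed when missing.
#' @param method Raw estimation method (see \code{\link{fit_gene_models}}).
#' @param n_boot Number of bootstrap resamples (default 13).
#' @param seed Integer seed; deterministic given the seed.
#' @param genes Optional gene subset to fit (speed).
#' @param regularized Also track regularized parameters per bootstrap.
#' @param baf Bandwidth adjustment factor for the regularized track.
#' @return \code{data.frame} with columns \code{gene_id}, \code{parameter}
#'   (\code{beta0}, \code{beta1}, \code{theta}), \code{kind} (\code{raw}
#'   or \code{regularized}), \code{bootstrap_mean}, \code{bootstrap_sd},
#'   \code{uncertainty_score}, \code{n_boot_used}.
#' @export
bootstrap_uncertainty <- function(counts, depths = NULL,
                                  method = "poisson_theta",
                                  n_boot = 13, seed = NULL,
                                  genes = NULL, regularized = FALSE,
                                  baf = 3) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  counts <- validate_counts(counts)
  if (is.null(depths)) depths <- Matrix::colSums(counts)
  if (is.null(genes)) genes <- rownames(counts)
  params <- c("beta0", "beta1", "theta")

  est <- with_seed(seed, {
    raw_a <- array(NA_real_, dim = c(length(genes), 3, n_boot),
                   dimnames = list(genes, params, NULL))
    reg_a <- if (regularized) raw_a else NULL
    for (b in seq_len(n_boot)) {
      take <- sample.int(ncol(counts), ncol(counts), replace = TRUE)
      cb <- counts[, take, drop = FALSE]
      colnames(cb) <- make.unique(colnames(counts)[take], sep = ".")
      fit <- tryCatch(
        fit_gene_models(cb, depths[take], method = method, genes = genes),
        error = function(e) NULL)
      if (is.null(fit)) next
      k <- match(fit$gene_id, genes)
      raw_a[k, , b] <- as.matrix(fit[, params])
      # a capped dispersion is a boundary fit with no finite ML estimate:
      # it carries no information about theta's sampling variability
      raw_a[k[fit$theta >= 0.99 * theta_cap_default], "theta", b] <- NA
      if (regularized) {
        gm <- gene_summary(counts)
        reg <- regularize(fit, gm[match(genes, gm$gene_id), ], baf = baf)
        kr <- match(reg$gene_id, genes)
        reg_a[kr, , b] <- as.matrix(reg[, params])
      }
    }
    list(raw = raw_a, reg = reg_a)
  })

  score_tab <- function(a, kind) {
    bm <- apply(a, c(1, 2), mean, na.rm = TRUE)
    bs <- apply(a, c(1, 2), stats::sd, na.rm = TRUE)
    nb <- apply(a, c(1, 2), function(v) sum(is.finite(v)))
    denom <- apply(bm, 2, stats::sd, na.rm = TRUE)
    data.frame(gene_id = rep(genes, times = 3),
               parameter = rep(params, each = length(genes)),
               kind = kind,
               bootstrap_mean = as.vector(bm),
               bootstrap_sd = as.vector(bs),
               uncertainty_score = as.vector(sweep(bs, 2, denom, "/")),
               n_boot_used = as.vector(nb),
               stringsAsFactors = FALSE)
  }
  out <- score_tab(est$raw, "raw")
  if (regularized) out <- rbind(out, score_tab(est$reg, "regularized"))
  rownames(out) <- NULL
  out
}

#' Uncertainty scores from a gene x bootstrap estimate matrix
#'
#' The score of gene g is \code{sd(estimates of g across bootstraps) /
#' sd(bootstrap-mean values across genes)}. Exposed separately so the
#' arithmetic can be applied to externally produced bootstrap tables.
#'
#' @param estimates Numeric matrix, genes x bootstraps, for one parameter.
#' @return \code{data.frame} with \code{bootstrap_mean},
#'   \code{bootstrap_sd}, \code{uncertainty_score} per gene.
#' @export
uncertainty_scores <- function(estimates) {
  bm <- rowMeans(estimates, na.rm = TRUE)
  bs <- apply(estimates, 1, stats::sd, na.rm = TRUE)
  denom <- stats::sd(bm, na.rm = TRUE)
  data.frame(gene_id = rownames(estimates) %||% seq_len(nrow(estimates)),
             bootstrap_mean = unname(bm), bootstrap_sd = unname(bs),
             uncertainty_score = unname(bs / denom),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald confidence intervals for model parameters
#'
#' \code{estimate +/- 1.96 * SE} at the default 95% level, from the
#' Fisher-information standard errors recorded in the raw model table.
#' Genes missing an SE get \code{NA} bounds.
#'
#' @param model Raw model table from \code{\link{fit_gene_models}}.
#' @param level Confidence level.
#' @return \code{data.frame} with lower/upper bounds for each of
#'   \code{beta0}, \code{beta1}, \code{theta}.
#' @export
confidence_intervals <- function(model, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(gene_id = model$gene_id, stringsAsFactors = FALSE)
  for (p in c("beta0", "beta1", "theta")) {
    se <- model[[paste0("se_", p)]]
    out[[paste0(p, "_lower")]] <- model[[p]] - z * se
    out[[paste0(p, "_upper")]] <- model[[p]] + z * se
  }
  out
}

#' Bin genes by abundance
#'
#' Equal-width bins on log10 geometric mean spanning the observed range;
#' the maximum falls in the top bin. Six bins reproduce the grouping used
#' throughout the trend and variance-contribution diagnostics.
#'
#' @param gene_means Named numeric vector of gene means (> 0), or a
#'   \code{gene_summary} table.
#' @param n_bins Number of bins.
#' @return Named integer vector of bin assignments (1 = least abundant).
#' @export
bin_genes <- function(gene_means, n_bins = 6) {
  if (is.data.frame(gene_means)) {
    gene_means <- stats::setNames(gene_means$gmean, gene_means$gene_id)
  }
  if (any(gene_means <= 0)) stop("gene means must be positive for binning")
  lg <- log10(gene_means)
  if (diff(range(lg)) == 0) {
    warning("all gene means identical; single occupied bin")
    return(stats::setNames(rep(1L, length(lg)), names(lg)))
  }
  br <- seq(min(lg), max(lg), length.out = n_bins + 1)
  bin <- findInterval(lg, br, rightmost.closed = TRUE)
  stats::setNames(as.integer(bin), names(gene_means))
}

#' Expression trends versus sequencing depth
#'
#' For every gene, smooths its (raw or normalized) values against log10
#' depth with a normal-kernel regression at a deliberately large bandwidth
#' (20x the Sheather-Jones suggestion), then summarizes each gene group by
#' the quartiles of the smoothed curves at 200 equidistant points on the
#' log10-depth axis, restricted to the central 90% of cells by depth. Flat
#' bands at 0 after normalization indicate depth independence.
#'
#' @param values Gene x cell matrix (counts, log-normalized, or residuals).
#' @param depths Per-cell depths.
#' @param groups Gene-group assignment from \code{\link{bin_genes}}.
#' @param n_points Number of evaluation points (default 200).
#' @param bw_factor Multiplier on the Sheather-Jones bandwidth (default 20).
#' @param central_frac Fraction of cells (centered on the depth median)
#'   used (default 0.9).
#' @return List with \code{depth_grid} (evaluation depths) and
#'   \code{bands}: one matrix per group, rows \code{q25}, \code{q50},
#'   \code{q75}, columns the grid; groups with fewer than 3 genes are
#'   \code{NA}.
#' @export
expression_trend <- function(values, depths, groups, n_points = 200,
                             bw_factor = 20, central_frac = 0.9) {
  stopifnot(ncol(values) == length(depths))
  lo <- stats::quantile(depths, (1 - central_frac) / 2)
  hi <- stats::quantile(depths, 1 - (1 - central_frac) / 2)
  use <- depths >= lo & depths <= hi
  lg <- log10(depths[use])
  grid <- seq(min(lg), max(lg), length.out = n_points)
  bw <- sj_bandwidth(lg) * bw_factor

  genes <- intersect(rownames(values), names(groups))
  smoothed <- matrix(NA_real_, nrow = length(genes), ncol = n_points,
                     dimnames = list(genes, NULL))
  vals <- as.matrix(values[genes, use, drop = FALSE])
  for (k in seq_along(genes)) {
    smoothed[k, ] <- kernel_smooth(grid, lg, vals[k, ], bandwidth = bw)
  }

  bands <- lapply(sort(unique(groups)), function(g) {
    members <- intersect(names(groups)[groups == g], genes)
    if (length(members) < 3) {
      message("gene group ", g, " has fewer than 3 genes; band is NA")
      return(matrix(NA_real_, nrow = 3, ncol = n_points,
                    dimnames = list(c("q25", "q50", "q75"), NULL)))
    }
    apply(smoothed[members, , drop = FALSE], 2, stats::quantile,
          probs = c(0.25, 0.5, 0.75)) |>
      `rownames<-`(c("q25", "q50", "q75"))
  })
  names(bands) <- paste0("group_", sort(unique(groups)))
  list(depth_grid = 10^grid, bands = bands)
}

#' Sampling uncertainty of depth-bin variance contributions
#'
#' Bootstrap standard errors of the \code{\link{variance_contribution}}
#' fractions, resampling genes within each gene group with replacement.
#' For groups of rare genes the total squared deviation concentrates in a
#' few (clipped) burst counts, so the group share is a noisy statistic at
#' small gene counts; the SE quantifies whether a share estimate can
#' support a given tolerance.
#'
#' @inheritParams variance_contribution
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return Matrix gene-group x cell-bin of bootstrap SEs, aligned with
#'   \code{\link{variance_contribution}}.
#' @export
variance_contribution_se <- function(values, depths, groups,
                                     n_cell_bins = 5, n_boot = 200,
                                     seed = NULL) {
  stopifnot(ncol(values) == length(depths))
  n <- length(depths)
  ord <- order(-depths, seq_len(n))
  size <- n %/% n_cell_bins
  bin_of <- integer(n)
  bin_of[ord] <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_cell_bins)

  genes <- intersect(rownames(values), names(groups))
  vals <- as.matrix(values[genes, , drop = FALSE])
  sq <- (vals - rowMeans(vals))^2
  # per gene, squared-deviation mass per depth bin
  mass <- vapply(seq_len(n_cell_bins),
                 function(b) rowSums(sq[, bin_of == b, drop = FALSE]),
                 numeric(length(genes)))
  gene_groups <- sort(unique(groups))
  out <- matrix(NA_real_, nrow = length(gene_groups), ncol = n_cell_bins,
                dimnames = list(paste0("group_", gene_groups),
                                paste0("bin_", seq_len(n_cell_bins))))
  with_seed(seed, {
    for (gi in seq_along(gene_groups)) {
      members <- which(genes %in% names(groups)[groups == gene_groups[gi]])
      if (length(members) < 2) next
      reps <- vapply(seq_len(n_boot), function(r) {
        take <- sample(members, length(members), replace = TRUE)
        m <- colSums(mass[take, , drop = FALSE])
        if (sum(m) == 0) rep(NA_real_, n_cell_bins) else m / sum(m)
      }, numeric(n_cell_bins))
      out[gi, ] <- apply(reps, 1, stats::sd, na.rm = TRUE)
    }
  })
  out
}

#' Depth-bin contributions to gene-group variance
#'
#' Cells are placed in \code{n_cell_bins} equal-sized groups by total UMI
#' (bin 1 deepest; any remainder goes to the shallowest bin; depth ties
#' broken by cell index). Each gene is centered and squared, and a bin's
#' contribution to a gene group is the sum of squared deviations of the
#' group's genes in that bin divided by the sum over all cells. Under
#' depth-independent normalization every bin should contribute about
#' \code{1/n_cell_bins} of the variance.
#'
#' @param values Gene x cell matrix.
#' @param depths Per-cell depths.
#' @param groups Gene-group assignment from \code{\link{bin_genes}}.
#' @param n_cell_bins Number of depth bins (default 5).
#' @return Matrix gene-group x cell-bin of fractions summing to 1 per row
#'   (rows of groups with zero total variance are \code{NA}).
#' @export
variance_contribution <- function(values, depths, groups, n_cell_bins = 5) {
  stopifnot(ncol(values) == length(depths))
  if (n_cell_bins < 2) stop("need at least 2 cell bins")
  n <- length(depths)
  ord <- order(-depths, seq_len(n))
  size <- n %/% n_cell_bins
  bin_of <- integer(n)
  # deepest cells first; remainder cells join the shallowest bin
  bin_of[ord] <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_cell_bins)

  gene_groups <- sort(unique(groups))
  out <- matrix(NA_real_, nrow = length(gene_groups), ncol = n_cell_bins,
                dimnames = list(paste0("group_", gene_groups),
                                paste0("bin_", seq_len(n_cell_bins))))
  genes <- intersect(rownames(values), names(groups))
  vals <- as.matrix(values[genes, , drop = FALSE])
  sq <- (vals - rowMeans(vals))^2
  for (gi in seq_along(gene_groups)) {
    members <- intersect(names(groups)[groups == gene_groups[gi]], genes)
    if (!length(members)) next
    dev <- sq[members, , drop = FALSE]
    total <- sum(dev)
    if (total == 0) next  # row stays NA: contributions undefined
    out[gi, ] <- vapply(seq_len(n_cell_bins),
                        function(b) sum(dev[, bin_of == b]) / total,
                        numeric(1))
  }
  out
}
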