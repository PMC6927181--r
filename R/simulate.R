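# Synthetic UMI data with known ground truth: homogeneous populations,
# the two-group planted-DE design, and binomial-thinning depth
# downsampling.

#' Synthetic per-gene ground-truth parameter table
#'
#' Builds a parameter table shaped like the regularization curves observed
#' in droplet-based PBMC data, for use when no real dataset is available
#' to learn base parameters from. Geometric gene means follow a
#' right-skewed distribution — log10(gmean) is normal with mean -1.5 and
#' SD 1, truncated to \code{gmean_range} — reproducing the bottom-heavy
#' abundance profile of real UMI data, where most genes are rare and only
#' about 1% exceed 10 counts per cell (\code{shape = "loguniform"} gives
#' the flat alternative). The slope is fixed at \code{log(10)} so expected
#' counts are proportional to depth; the intercept anchors the expected
#' count at the reference depth to the gene mean
#' (\code{beta0 = log(gmean) - beta1 * log10(depth_ref)}); and dispersion
#' follows \code{log10(theta) = 1 + log10(gmean)} — roughly 0.03 for the
#' rarest genes up to a few hundred for abundant ones, mirroring the
#' increasing theta-versus-abundance trend of real UMI data.
#'
#' @param n_genes Number of genes.
#' @param gmean_range Truncation range of the geometric means (counts).
#' @param shape Abundance distribution: \code{"lognormal"} (default,
#'   realistic) or \code{"loguniform"} (flat across the log range).
#' @param depth_ref Reference depth at which the expected count equals the
#'   gene mean; defaults to the median of the lognormal depth generator.
#' @param theta Optional fixed dispersion overriding the abundance trend
#'   (scalar or per-gene vector), e.g. \code{theta = 1} for a strongly
#'   overdispersed fixture.
#' @param seed Integer seed.
#' @return \code{data.frame} with \code{gene_id}, \code{gmean},
#'   \code{beta0}, \code{beta1}, \code{theta}.
#' @export
simulate_gene_params <- function(n_genes = 500,
                                 gmean_range = c(10^-2.5, 10^1.5),
                                 shape = c("lognormal", "loguniform"),
                                 depth_ref = exp(7.5),
                                 theta = NULL,
                                 seed = NULL) {
  shape <- match.arg(shape)
  lo <- log10(gmean_range[1])
  hi <- log10(gmean_range[2])
  gmean <- with_seed(seed, {
    lg <- if (shape == "loguniform") {
      stats::runif(n_genes, lo, hi)
    } else {
      # truncated normal by inversion: exact, no rejection loop
      p <- stats::runif(n_genes, stats::pnorm(lo, -1.5, 1),
                        stats::pnorm(hi, -1.5, 1))
      stats::qnorm(p, -1.5, 1)
    }
    10^lg
  })
  gmean <- sort(gmean)
  beta1 <- rep(log(10), n_genes)
  beta0 <- log(gmean) - beta1 * log10(depth_ref)
  th <- if (is.null(theta)) 10^(1 + log10(gmean)) else rep(theta, length.out = n_genes)
  if (any(th <= 0)) stop("theta must be positive")
  data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
             gmean = gmean, beta0 = beta0, beta1 = beta1, theta = th,
             stringsAsFactors = FALSE)
}

#' Draw per-cell sequencing depths
#'
#' Samples with replacement from an empirical depth vector when one is
#' given, otherwise draws lognormal depths (meanlog 7.5, sdlog 0.35,
#' median about 1800 UMI) resembling the depth scale of droplet PBMC
#' libraries.
#'
#' @param n_cells Number of depths to draw.
#' @param empirical Optional vector of observed depths to resample.
#' @param meanlog,sdlog Lognormal parameters for the generator fallback.
#' @param seed Integer seed.
#' @return Numeric vector of depths (rounded to whole UMIs, min 1).
#' @export
simulate_depths <- function(n_cells, empirical = NULL,
                            meanlog = 7.5, sdlog = 0.35, seed = NULL) {
  with_seed(seed, {
    m <- if (!is.null(empirical)) {
      sample(empirical, n_cells, replace = TRUE)
    } else {
      stats::rlnorm(n_cells, meanlog, sdlog)
    }
    pmax(round(m), 1)
  })
}

nb_draw <- function(n, mu, theta, cap = theta_cap_default) {
  if (any(!is.finite(mu))) stop("non-finite NB mean")
  if (theta >= cap) stats::rpois(n, mu) else stats::rnbinom(n, size = theta, mu = mu)
}

#' Simulate a homogeneous cell population
#'
#' Draws a depth for every cell, computes the model-implied mean
#' \code{mu_ij = exp(beta0_i + beta1_i log10 m_j)} and samples
#' \code{x_ij ~ NB(mu_ij, theta_i)}. All cells belong to one population;
#' every gene is labeled non-DE.
#'
#' @param gene_params Truth table as from \code{\link{simulate_gene_params}}.
#' @param n_cells Number of cells.
#' @param depths Optional empirical depth vector to resample (see
#'   \code{\link{simulate_depths}}).
#' @param seed Integer seed; counts are bit-identical given the seed.
#' @return List of class \code{synthetic_dataset}: \code{counts} (sparse),
#'   \code{group_labels}, \code{de_labels}, \code{truth} (the parameter
#'   table used), \code{depth_drawn}.
#' @export
simulate_homogeneous <- function(gene_params, n_cells = 2000, depths = NULL,
                                 seed = NULL) {
  with_seed(seed, {
    m <- simulate_depths(n_cells, empirical = depths)
    counts <- draw_counts(gene_params, m)
    structure(list(counts = counts,
                   group_labels = rep("A", n_cells),
                   de_labels = rep("null", nrow(gene_params)),
                   truth = gene_params,
                   depth_drawn = m),
              class = "synthetic_dataset")
  })
}

draw_counts <- function(gene_params, m, cell_prefix = "cell") {
  n_cells <- length(m)
  log10_m <- log10(m)
  x <- matrix(0L, nrow = nrow(gene_params), ncol = n_cells)
  for (i in seq_len(nrow(gene_params))) {
    mu <- exp(gene_params$beta0[i] + gene_params$beta1[i] * log10_m)
    if (any(!is.finite(mu))) stop("non-finite mean for gene ",
                                  gene_params$gene_id[i])
    x[i, ] <- nb_draw(n_cells, mu, gene_params$theta[i])
  }
  counts <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(gene_params$gene_id,
                           sprintf("%s%05d", cell_prefix, seq_len(n_cells)))
  counts
}

#' Simulate two cell populations with planted differential expression
#'
#' Generates populations A and B. A fraction \code{frac_up} of genes is
#' chosen to be higher in A and a disjoint \code{frac_down} higher in B,
#' with mean ratio \code{fold} between groups: the gene mean is multiplied
#' by \code{sqrt(fold)} in the up group and divided by \code{sqrt(fold)} in
#' the down group. The intercept shifts by \code{+/- log(fold)/2}
#' accordingly, while slope and dispersion are re-read from regularization
#' curves (kernel regressions of the base table's parameters on log10 gene
#' mean) evaluated at the shifted gene mean, so DE genes remain on the
#' global parameter manifold. Cells are generated in pairs, one per group,
#' with depths drawn independently per cell.
#'
#' @param gene_params Base truth table.
#' @param n_cells_per_group Cells in each of A and B (default 5000).
#' @param frac_up,frac_down Fractions of genes up in A / up in B
#'   (default 0.05 each; must sum to at most 1).
#' @param fold Mean ratio between groups for DE genes (default 10, > 1).
#' @param depths Optional empirical depth vector.
#' @param seed Integer seed.
#' @return \code{synthetic_dataset} with \code{group_labels} in
#'   \code{c("A","B")}, \code{de_labels} in
#'   \code{c("up_in_A","up_in_B","null")} and per-group truth tables in
#'   \code{truth}.
#' @export
simulate_two_groups <- function(gene_params, n_cells_per_group = 5000,
                                frac_up = 0.05, frac_down = 0.05,
                                fold = 10, depths = NULL, seed = NULL) {
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (fold <= 1) stop("fold must be > 1")
  n_genes <- nrow(gene_params)
  n_up <- round(frac_up * n_genes)
  n_down <- round(frac_down * n_genes)

  with_seed(seed, {
    pick <- sample.int(n_genes, n_up + n_down)
    up <- pick[seq_len(n_up)]
    down <- pick[n_up + seq_len(n_down)]
    de_labels <- rep("null", n_genes)
    de_labels[up] <- "up_in_A"
    de_labels[down] <- "up_in_B"

    # regularization curves of the base table, for re-deriving slope and
    # dispersion at the shifted gene means
    lg <- log10(gene_params$gmean)
    bw1 <- tryCatch(sj_bandwidth(lg) * 3, error = function(e) 1)
    curve_beta1 <- function(g) kernel_smooth(log10(g), lg,
                                             gene_params$beta1, bw1)
    curve_theta <- function(g) 10^kernel_smooth(log10(g), lg,
                                                log10(gene_params$theta), bw1)

    shift_group <- function(sign_up, sign_down) {
      p <- gene_params
      shift <- rep(0, n_genes)
      shift[up] <- sign_up * log(fold) / 2
      shift[down] <- sign_down * log(fold) / 2
      p$gmean <- p$gmean * exp(shift)
      p$beta0 <- p$beta0 + shift
      moved <- c(up, down)
      p$beta1[moved] <- curve_beta1(p$gmean[moved])
      p$theta[moved] <- curve_theta(p$gmean[moved])
      p
    }
    truth_a <- shift_group(+1, -1)
    truth_b <- shift_group(-1, +1)

    m_a <- simulate_depths(n_cells_per_group, empirical = depths)
    m_b <- simulate_depths(n_cells_per_group, empirical = depths)
    counts <- cbind(draw_counts(truth_a, m_a, cell_prefix = "A_"),
                    draw_counts(truth_b, m_b, cell_prefix = "B_"))

    structure(list(counts = counts,
                   group_labels = rep(c("A", "B"), each = n_cells_per_group),
                   de_labels = de_labels,
                   truth = list(A = truth_a, B = truth_b),
                   depth_drawn = c(m_a, m_b)),
              class = "synthetic_dataset")
  })
}

#' Downsample UMI counts by binomial thinning
#'
#' Thins every count of the selected cells binomially with retention
#' probability \code{fraction}, emulating shallower sequencing: the
#' expected depth of a thinned cell is \code{fraction} times its original
#' depth. Thinning is independent per matrix entry; at UMI count
#' magnitudes this is indistinguishable from the per-cell hypergeometric
#' draw of subsampling reads.
#'
#' @param counts Gene x cell count matrix.
#' @param fraction Retention probability in (0, 1].
#' @param cells Optional cell identifiers (or indices) to thin; all cells
#'   by default. An empty subset returns the matrix unchanged with a
#'   warning.
#' @param seed Integer seed.
#' @return Count matrix of the same shape.
#' @export
downsample_umis <- function(counts, fraction, cells = NULL, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (fraction == 1) return(counts)
  if (is.null(cells)) {
    take <- seq_len(ncol(counts))
  } else if (is.character(cells)) {
    take <- match(cells, colnames(counts))
    if (anyNA(take)) stop("unknown cell identifier(s)")
  } else {
    take <- cells
  }
  if (length(take) == 0L) {
    warning("empty cell subset; returning counts unchanged")
    return(counts)
  }
  with_seed(seed, {
    sub <- counts[, take, drop = FALSE]
    sub@x <- as.numeric(stats::rbinom(length(sub@x), size = sub@x,
                                      prob = fraction))
    out <- counts
    out[, take] <- sub
    Matrix::drop0(out)
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic UMI dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells\n")
  cat("  groups:", paste(names(table(x$group_labels)),
                         table(x$group_labels), sep = "=", collapse = ", "),
      "\n")
  de <- table(x$de_labels)
  cat("  DE labels:", paste(names(de), de, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
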