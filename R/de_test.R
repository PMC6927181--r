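# Two-group differential expression on normalized values with a
# permutation-derived background threshold on mean differences and BH FDR
# control.

#' Permutation background thresholds for mean differences
#'
#' Chooses \code{n_background} genes at random (with replacement, with a
#' warning, when fewer are available), permutes the group labels once per
#' chosen gene and records the resulting group mean difference. The 0.5th
#' and 99.5th percentiles of these null differences are returned as the
#' significance thresholds a real mean difference must exceed.
#'
#' @param values Gene x cell matrix of normalized values.
#' @param labels Two-group assignment, one label per cell.
#' @param n_background Number of background genes (default 1000).
#' @param n_draws Permutations per background gene (default 1; more give
#'   smoother thresholds).
#' @param seed Integer seed.
#' @return Named numeric vector \code{c(lower, upper)}.
#' @export
background_thresholds <- function(values, labels, n_background = 1000,
                                  n_draws = 1, seed = NULL) {
  labels <- as.character(labels)
  gl <- unique(labels)
  if (length(gl) != 2) stop("labels must define exactly two groups")
  if (!all(table(labels) > 0)) stop("both groups must be nonempty")
  n_genes <- nrow(values)
  with_seed(seed, {
    replace <- n_background > n_genes
    if (replace) {
      warning("fewer genes (", n_genes, ") than n_background (",
              n_background, "); sampling with replacement")
    }
    pick <- sample.int(n_genes, n_background, replace = replace)
    diffs <- numeric(n_background * n_draws)
    n <- ncol(values)
    n1 <- sum(labels == gl[1])
    for (k in seq_along(pick)) {
      v <- as.numeric(values[pick[k], ])
      for (d in seq_len(n_draws)) {
        perm <- sample.int(n, n1)
        in1 <- logical(n)
        in1[perm] <- TRUE
        diffs[(k - 1) * n_draws + d] <- mean(v[in1]) - mean(v[!in1])
      }
    }
    q <- stats::quantile(diffs, c(0.005, 0.995), names = FALSE)
    c(lower = q[1], upper = q[2])
  })
}

# Vectorized Welch two-sample t-test across the rows of a matrix.
welch_rows <- function(values, in1) {
  v <- as.matrix(values)
  n1 <- sum(in1)
  n2 <- sum(!in1)
  m1 <- rowMeans(v[, in1, drop = FALSE])
  m2 <- rowMeans(v[, !in1, drop = FALSE])
  s1 <- rowSums((v[, in1, drop = FALSE] - m1)^2) / (n1 - 1)
  s2 <- rowSums((v[, !in1, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_var <- se2 == 0
  t_stat[zero_var] <- 0
  p[zero_var] <- 1  # no variance in either group: no evidence, not an error
  list(mean_diff = m1 - m2, t_stat = t_stat, p_value = p)
}

#' Differential expression between two groups
#'
#' Welch two-sample t-tests per gene on normalized values (Pearson
#' residuals or log-normalized expression), for all genes detected in at
#' least \code{min_cells_detected} cells in at least one of the groups.
#' P-values are Benjamini-Hochberg adjusted, and a gene is called
#' significant only when its FDR is below \code{alpha} AND its group mean
#' difference lies outside the permutation background thresholds of
#' \code{\link{background_thresholds}}.
#'
#' @param values Gene x cell matrix of normalized values.
#' @param labels Two-group assignment per cell; the first group in sort
#'   order is the reference of \code{mean_diff} (group1 - group2).
#' @param counts Optional raw count matrix used to evaluate detection
#'   ("detected" = nonzero count); detection falls back to nonzero
#'   normalized values when missing.
#' @param min_cells_detected Detection threshold (default 5 cells).
#' @param alpha FDR threshold (default 0.01).
#' @param n_background,n_draws,seed Passed to
#'   \code{\link{background_thresholds}}.
#' @return \code{data.frame} with per-gene \code{mean_diff}, \code{t_stat},
#'   \code{p_value}, \code{fdr}, \code{significant}; thresholds in
#'   attribute \code{"thresholds"}.
#' @export
differential_expression <- function(values, labels, counts = NULL,
                                    min_cells_detected = 5, alpha = 0.01,
                                    n_background = 1000, n_draws = 1,
                                    seed = NULL) {
  labels <- as.character(labels)
  gl <- sort(unique(labels))
  if (length(gl) != 2) stop("labels must define exactly two groups")
  in1 <- labels == gl[1]

  det_src <- if (!is.null(counts)) counts else values
  det_src <- det_src[rownames(values), , drop = FALSE]
  det1 <- Matrix::rowSums(det_src[, in1, drop = FALSE] != 0)
  det2 <- Matrix::rowSums(det_src[, !in1, drop = FALSE] != 0)
  eligible <- det1 >= min_cells_detected | det2 >= min_cells_detected

  thr <- background_thresholds(values, labels, n_background = n_background,
                               n_draws = n_draws, seed = seed)
  tt <- welch_rows(values[eligible, , drop = FALSE], in1)
  fdr <- stats::p.adjust(tt$p_value, method = "BH")
  out <- data.frame(gene_id = rownames(values)[eligible],
                    mean_diff = unname(tt$mean_diff),
                    t_stat = unname(tt$t_stat),
                    p_value = unname(tt$p_value),
                    fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < alpha &
    (out$mean_diff < thr["lower"] | out$mean_diff > thr["upper"])
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  attr(out, "groups") <- gl
  out
}
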