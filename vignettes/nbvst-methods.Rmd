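---
title: "Methods: regularized NB regression for UMI count normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized NB regression for UMI count normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbvst)
```

## The problem

UMI counts from droplet single-cell RNA-seq confound biology with the
number of molecules each cell happened to yield. Dividing by a single
size factor and taking logs does not fix this: a scale factor that
stabilizes abundant genes leaves rare genes under-corrected, and vice
versa, because the variance of a count depends on its mean in a way no
global transformation matches across four decades of gene abundance.

`nbvst` instead models each gene's counts explicitly and returns what the
model cannot explain. For gene $i$ and cell $j$ with library depth
$m_j = \sum_i x_{ij}$:

$$\log \mathbb{E}(x_{ij}) = \beta_{0i} + \beta_{1i}\,\log_{10} m_j,$$

with negative binomial error, variance $\mu + \mu^2/\theta$. The link is
the natural log but the covariate is $\log_{10}$ depth, so $\beta_1$ is
"per decade of depth" ($\beta_1 = \ln 10 \approx 2.303$ means counts
proportional to depth). The normalized value is the Pearson residual of
the **regularized** model,

$$z_{ij} = \frac{x_{ij} - \mu_{ij}}{\sigma_{ij}}, \qquad
\mu_{ij} = e^{\beta_{0i} + \beta_{1i}\log_{10} m_j}, \qquad
\sigma_{ij} = \sqrt{\mu_{ij} + \mu_{ij}^2/\theta_i},$$

clipped to $\pm\sqrt{N}$ ($N$ = number of cells). On data with no real
heterogeneity the residuals have mean 0 and variance 1 per gene; genes
whose residual variance exceeds 1 carry variation the technical model
does not explain, which is exactly what a highly-variable-gene ranking
should measure.

## The three steps

1. **Independent per-gene fits.** By default the coefficients are
   estimated under Poisson error (IRLS) and $\theta$ by maximum
   likelihood given the fitted means (`method = "poisson_theta"`). Two
   costlier variants — an NB re-fit of the coefficients with $\theta$
   fixed, and a full alternating NB iteration — give nearly identical
   residuals; the test suite checks median per-gene residual
   correlations above 0.99 between all three. Fitting can be restricted
   to a subset of genes (default 2000) sampled with probability
   proportional to the inverse density of $\log_{10}$ gene mean, so the
   whole abundance range is covered evenly.
2. **Regularization.** Raw per-gene estimates overfit, badly so for rare
   genes. Each parameter is therefore replaced by a smooth function of
   $\log_{10}$ geometric gene mean, learned across genes:
   kernel-weighted regression with a Gaussian kernel whose bandwidth is
   the Sheather–Jones plug-in value times a bandwidth adjustment factor
   (BAF, default 3). $\beta_0$ and $\beta_1$ are smoothed on their
   natural scale, $\theta$ as $\log_{10}\theta$ (positivity, heavy right
   tail). Dispersion estimates at the cap (see below) are excluded from
   the $\theta$ smoother: they are boundary fits, not ML estimates.
3. **Transform.** All genes — including those never fitted raw — receive
   parameters from the smooth curves evaluated at their gene mean, and
   counts become clipped Pearson residuals.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_cells` | 5 | keep genes detected (nonzero) in at least this many cells |
| `n_genes` | 2000 | size of the estimation gene subset |
| `method` | `poisson_theta` | per-gene estimation method |
| `baf` | 3 | bandwidth adjustment factor; residual variances change by <5% over 1–10 |
| `smoother` | `local_linear` | regularization regression (see below) |
| `eps` | 1 | pseudo-offset of the geometric mean $\exp(\mathrm{mean}\log(x+\epsilon))-\epsilon$ |
| `theta_cap` | $10^6$ | upper bound for $\theta$ (indistinguishable from Poisson) |
| `clip` | `sqrt_n` | residual clipping at $\pm\sqrt N$ |
| `depths` | column sums | per-cell library totals (see below) |

The geometric mean (with $\epsilon = 1$) rather than the arithmetic mean
is used as the abundance axis everywhere: it damps outlier cells and
respects the exponential character of the counts.

## Design choices that were genuinely open

**Local-linear smoothing.** The classical constant-fit (Nadaraya–Watson)
kernel average is unbiased only where the design is dense and the trend
locally flat. The $\beta_0$ trend is steep ($\approx \ln 10$ per decade)
and the abundant end of the gene-mean axis is sparse, so at the scale of
a few hundred genes the constant fit shifts $\mu$ for abundant genes by
up to tens of percent — inflating residual variances and bending the
depth-trend diagnostics exactly where the model claims flatness. A
kernel-weighted *line* through each evaluation point (same Gaussian
kernel, same quartile bandwidth convention, same SJ×BAF bandwidth)
removes this first-order bias; both smoothers agree closely away from
the extremes, and `smoother = "kernel"` restores the classical variant.
Regularized values are clamped to the range of the raw estimates
entering the smoother — they are summaries of raw fits, never
extrapolations beyond them. Queries outside the fitted abundance range
receive the nearest evaluable estimate.

**Dispersion at the boundary.** ML for $\theta$ diverges whenever the
sample shows no excess variance over Poisson; such fits are returned at
`theta_cap` with a boundary flag, excluded from the $\theta$ smoother
and from bootstrap dispersion statistics (a gene capped in every
bootstrap would otherwise report zero uncertainty).

**The depth covariate.** Depth is a property of the whole library. When
the modeled matrix is a subset of the transcriptome — as in the
simulated fixtures, which represent a window of 500–3000 genes from a
cell with a realistic total — the partial column sum is a noisy proxy
(9% CV at 500 genes) and the true library total should be supplied via
`depths`. On full matrices the column sums are the library totals and
the default is correct.

**Clipping is symmetric.** Negative residuals are bounded near
$-\mu/\sigma$ by construction; the symmetric clip at $\pm\sqrt N$ guards
extreme high-depth cells as well. Clipping touches well under 1% of
entries on homogeneous data.

**Covariate extension.** Nuisance covariates (batch, cell cycle) cannot
be regularized — genes of similar abundance need not respond similarly —
so they are fitted in a second per-gene NB regression in which the
depth part $\beta_{0i} + \beta_{1i}\log_{10} m_j$ enters as a fixed
offset and $\theta_i$ stays at its regularized value. Residuals of that
regression are the normalized values.

## The synthetic world

`simulate_gene_params()` builds the ground truth the generator draws
from, shaped like the regularization curves of droplet PBMC data:

* $\log_{10}$ gene means follow a truncated normal ($-1.5 \pm 1$,
  range $10^{-2.5}$–$10^{1.5}$): bottom-heavy, with roughly 1% of genes
  above 10 counts/cell, as in real UMI data. A log-uniform option
  exists but overpopulates the abundant boundary where any cross-gene
  smoother is least accurate.
* $\beta_1 = \ln 10$ (counts proportional to depth), $\beta_0$ anchored
  so the expected count at the median library depth equals the gene
  mean.
* $\log_{10}\theta = 1 + \log_{10}(\text{gmean})$: overdispersion
  strongest for rare genes, $\theta \approx 10$ at one count per cell.
* Library depths are drawn lognormal (meanlog 7.5, sdlog 0.35, median
  ≈ 1800 UMI) or resampled from an empirical vector.

The two-group design plants disjoint fractions of up/down genes
(default 5% each) with mean ratio `fold` (default 10), applied as
$\pm\tfrac12\ln(\text{fold})$ on $\beta_0$; slope and dispersion of the
shifted genes are re-read from regularization curves at the new mean, so
planted genes stay on the global parameter manifold.
`downsample_umis()` thins counts binomially — per-entry thinning, which
at UMI magnitudes is indistinguishable from per-cell subsampling of
reads.

What a green test on this world does establish: calibration of the full
pipeline (residual means 0, variance mode 1, uniform variance across
depth bins), sensitivity of the residual-variance ranking to planted
signal, and robustness of downstream DE to depth differences. What it
does not establish: behavior under ambient RNA, doublets, cell-type
mixtures, or the exact parameter values of any real tissue; the
generating curves are synthetic stand-ins, not estimates from the
reference dataset.

## Differential expression

Welch $t$-tests per gene on the normalized values, for genes detected in
at least 5 cells in one of the two groups; Benjamini–Hochberg FDR. A
gene is called only if, in addition to FDR < 0.01, its group mean
difference exceeds a background band: 1000 random genes are label-
permuted once each and the 0.5th/99.5th percentiles of their null mean
differences form the thresholds. The pooled-variance alternative is not
offered; Welch is the robust default for unequal group sizes.

## Numerical conventions

* Kernel scaling follows the classical smoother convention: quartiles at
  $\pm 0.25 \times$ bandwidth, i.e. Gaussian $\sigma = 0.3707 \times$
  bandwidth — bandwidth numbers are comparable across all smoothing
  steps.
* IRLS: deviance tolerance $10^{-8}$, 100 iterations. Alternating NB
  fits use the standard alternating iteration with its own convergence
  flag; non-convergent genes keep their best iterate, flagged.
* Sheather–Jones bandwidth falls back to Silverman's rule (with a
  warning) when the plug-in equation has no solution.
* Equal-width gene bins on $\log_{10}$ gmean put the maximum in the top
  bin; equal-sized depth bins rank deepest-first with ties broken by
  cell index, remainder cells joining the shallowest bin.
* Trend diagnostics evaluate at 200 points equidistant on the
  $\log_{10}$-depth axis (the axis the smoother operates on), within the
  central 90% of cells by depth, at 20× the SJ bandwidth.
* The uncertainty score of a gene/parameter pair is its bootstrap SD
  divided by the SD of bootstrap means across genes; it is reported, not
  thresholded.
* Depth-bin variance shares are a ratio statistic; for groups of rare
  genes the total squared deviation rests on a handful of clipped burst
  counts, so `variance_contribution_se()` provides gene-bootstrap SEs to
  judge whether a share supports a given tolerance at a given scale.

## Known limitations

* Parameters at both extremes of the abundance axis are estimated from
  few genes; local-linear smoothing removes the first-order bias but the
  estimates there remain the least certain.
* No zero-inflated model is offered (deliberately: extra zero mass
  invites overfitting on UMI data), and no imputation — residuals are
  the terminal product.
* Batch correction through the covariate extension is linear; cell-type
  specific batch effects need dedicated non-linear methods.
* Depth-dependent parameters are regularized; covariate coefficients are
  not, and rare genes' covariate estimates are noisy.

## A worked example

```{r example, eval = FALSE}
params <- simulate_gene_params(n_genes = 500, seed = 1)
sim <- simulate_homogeneous(params, n_cells = 2000, seed = 2)
fit <- nbvst(sim$counts, depths = sim$depth_drawn, seed = 3)
summary(fit)
plot(fit)   # raw estimates vs regularized curves

groups <- bin_genes(setNames(fit$gene_attr$gmean, fit$gene_attr$gene_id))
variance_contribution(fit$residuals, fit$cell_attr$depth, groups)
```
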