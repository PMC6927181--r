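# Fixture builders shared across test files. Everything is generated in
# code; the larger simulated datasets are memoized so multiple test files
# reuse one computation per run.

toy_counts <- function() {
  m <- Matrix::Matrix(matrix(c(1, 0, 2,
                               0, 3, 0,
                               4, 5, 6), nrow = 3, byrow = TRUE),
                      sparse = TRUE)
  dimnames(m) <- list(c("ACTB", "CD19", "MS4A1"),
                      c("cellA", "cellB", "cellC"))
  methods::as(m, "CsparseMatrix")
}

random_sparse_counts <- function(n_genes = 40, n_cells = 30, seed = 1,
                                 lambda = 0.8) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Mid-sized homogeneous NB simulation + full fit, shared across files.
shared_sim <- function() {
  memo("shared_sim", {
    params <- simulate_gene_params(n_genes = 300, seed = 201)
    simulate_homogeneous(params, n_cells = 1000, seed = 202)
  })
}

shared_fit <- function() {
  memo("shared_fit", {
    sim <- shared_sim()
    nbvst(sim$counts, n_genes = 300, seed = 203, verbose = FALSE)
  })
}

# Acceptance-scale homogeneous simulation (500 genes x 2000 cells).
acceptance_sim <- function() {
  memo("acceptance_sim", {
    params <- simulate_gene_params(n_genes = 500, seed = 101)
    simulate_homogeneous(params, n_cells = 2000, seed = 102)
  })
}

acceptance_fit <- function() {
  memo("acceptance_fit", {
    sim <- acceptance_sim()
    # depth covariate = the cell's full-library total (the simulated genes
    # are a window of a transcriptome whose total UMI is the drawn depth)
    nbvst(sim$counts, depths = sim$depth_drawn, n_genes = 2000, seed = 103,
          verbose = FALSE)
  })
}
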