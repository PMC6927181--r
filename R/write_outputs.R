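#' Write the outputs of a fitted model to a directory
#'
#' Serializes the normalized residual matrix (\code{residuals.tsv}), the
#' per-gene summary (\code{gene_summary.tsv}), the raw and regularized
#' model tables (\code{model_raw.tsv}, \code{model.tsv}), and a JSON run
#' manifest (\code{manifest.json}) recording the settings, seed and
#' bandwidths used.
#'
#' @param fit Fitted \code{\link{nbvst}} object.
#' @param dir Output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_nbvst <- function(fit, dir) {
  stopifnot(inherits(fit, "nbvst"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  res <- data.frame(gene_id = rownames(fit$residuals),
                    as.data.frame(fit$residuals, check.names = FALSE),
                    check.names = FALSE)
  wt(res, "residuals.tsv")
  wt(fit$gene_attr, "gene_summary.tsv")
  wt(fit$raw_models, "model_raw.tsv")
  wt(fit$model, "model.tsv")
  manifest <- c(fit$params[c("min_cells", "n_genes", "method", "baf",
                             "clip", "clip_value", "eps", "theta_cap",
                             "seed")],
                list(bandwidths = as.list(fit$params$bandwidths),
                     n_genes_modeled = nrow(fit$residuals),
                     n_cells = ncol(fit$residuals)))
  writeLines(to_json(manifest), file.path(dir, "manifest.json"))
  invisible(dir)
}

# minimal JSON writer for the flat manifest (jsonlite is only Suggested)
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(sprintf('"%s": %s', names(v),
                                vapply(v, enc, character(1))),
                        collapse = ", "), "}")
    } else if (is.character(v)) {
      sprintf('"%s"', v)
    } else if (is.numeric(v) && length(v) == 1) {
      format(v, digits = 15)
    } else if (is.numeric(v)) {
      paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
    } else if (is.logical(v)) {
      tolower(as.character(v))
    } else "null"
  }
  enc(as.list(x))
}
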