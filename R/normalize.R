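# Normalization and variable-gene selection.

#' Log-normalize a single-cell count matrix
#'
#' Per-cell library-size normalization followed by `log1p`:
#' `value(g, c) = ln(1 + scale_factor * count(g, c) / total_counts(c))`.
#' Cell annotations are preserved; the result is stored as a `logcounts`
#' assay when the input is a `SingleCellExperiment`.
#'
#' @param m labeled expression matrix (or a bare genes-by-cells count matrix).
#' @param scale_factor library-size scaling constant (default `1e4`).
#' @return The input object with a `logcounts` assay added (or, for a bare
#'   matrix input, the normalized matrix itself).
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  assert_positive(scale_factor, "scale_factor")
  counts <- get_assay(m, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop2("cell(s) with all-zero counts cannot be normalized: ",
          paste(utils::head(colnames(counts)[totals == 0], 10L), collapse = ", "))
  }
  if (inherits(counts, "sparseMatrix")) {
    norm <- counts
    norm@x <- log1p(scale_factor * norm@x /
                      rep.int(totals, diff(norm@p)))
  } else {
    norm <- log1p(scale_factor * sweep(counts, 2L, totals, "/"))
  }
  if (methods::is(m, "SummarizedExperiment")) {
    SummarizedExperiment::assay(m, "logcounts") <- norm
    m
  } else {
    norm
  }
}

#' Select highly variable genes by a variance-stabilizing transform
#'
#' Ranks genes by standardized variance in the Seurat-vst sense: a loess
#' mean-variance trend is fitted on (log10 mean, log10 variance) of the raw
#' counts, each gene's counts are standardized by the trend-predicted SD with
#' values clipped at `sqrt(n_cells)`, and genes are ranked by the variance of
#' the clipped standardized values.
#'
#' @param m labeled expression matrix (raw counts are used for the trend).
#' @param n_top number of genes to return (default 3000, capped at the number
#'   of genes with positive variance).
#' @param loess_span span of the mean-variance trend fit.
#' @return Character vector of gene names, ordered by decreasing standardized
#'   variance.
#' @export
select_variable_genes <- function(m, n_top = 3000L, loess_span = 0.3) {
  if (n_top <= 0) stop2("n_top must be a positive integer")
  counts <- as.matrix(get_assay(m, "counts"))
  if (n_top > nrow(counts)) stop2("n_top exceeds the number of genes")
  n_cells <- ncol(counts)
  gmean <- rowMeans(counts)
  gvar <- apply(counts, 1L, stats::var)
  std_var <- rep(0, nrow(counts))
  usable <- gvar > 0 & gmean > 0
  if (any(usable)) {
    fit <- stats::loess(log10(gvar[usable]) ~ log10(gmean[usable]),
                        span = loess_span, degree = 2)
    pred_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n_cells)
    idx <- which(usable)
    for (k in seq_along(idx)) {
      i <- idx[k]
      z <- (counts[i, ] - gmean[i]) / pred_sd[k]
      z <- pmin(z, clip)
      std_var[i] <- stats::var(z)
    }
  }
  ord <- order(-std_var, rownames(counts))
  rownames(counts)[ord][seq_len(n_top)]
}
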