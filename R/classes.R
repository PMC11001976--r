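#' Construct a labeled single-cell expression matrix
#'
#' The substrate of the pipeline: a genes-by-cells count matrix with per-cell
#' `condition` (malignant/normal), `subtype` and `patient` labels, held as a
#' [SingleCellExperiment::SingleCellExperiment] with a `counts` assay.
#'
#' @param counts genes-by-cells matrix of nonnegative integer counts (dense or
#'   `Matrix` sparse); rownames are gene names, colnames cell ids.
#' @param cells `data.frame` with columns `cell_id`, `condition`, `subtype`,
#'   `patient`, one row per matrix column (matched by `cell_id`).
#' @return A `SingleCellExperiment` carrying the labels in its `colData`.
#' @export
labeled_expression_matrix <- function(counts, cells) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop2("counts must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop2("duplicate gene names in counts: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop2("duplicate cell ids in counts: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  required <- c("cell_id", "condition", "subtype", "patient")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop2("cell annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_cells <- setdiff(colnames(counts), cells$cell_id)
  if (length(missing_cells)) {
    stop2("cell annotation missing cell id(s): ", paste(missing_cells, collapse = ", "))
  }
  extra_cells <- setdiff(cells$cell_id, colnames(counts))
  if (length(extra_cells)) {
    stop2("cell annotation has unknown cell id(s): ", paste(extra_cells, collapse = ", "))
  }
  cells <- cells[match(colnames(counts), cells$cell_id), , drop = FALSE]
  bad <- setdiff(unique(cells$condition), c("malignant", "normal"))
  if (length(bad)) {
    stop2("condition labels must be 'malignant' or 'normal'; found: ",
          paste(bad, collapse = ", "))
  }
  if (any(is.na(cells$patient)) || any(is.na(cells$subtype))) {
    stop2("subtype and patient labels must be non-missing")
  }
  mal_no_subtype <- cells$condition == "malignant" & cells$subtype %in% c("", "none")
  if (any(mal_no_subtype)) {
    stop2("every malignant cell needs a subtype; offending cells: ",
          paste(utils::head(cells$cell_id[mal_no_subtype], 5L), collapse = ", "))
  }
  neg <- if (inherits(counts, "sparseMatrix")) any(counts@x < 0) else any(counts < 0)
  if (neg) stop2("counts must be nonnegative")
  cd <- S4Vectors::DataFrame(cells, row.names = cells$cell_id)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")),
    colData = cd
  )
}

#' Construct a perturbagen expression set
#'
#' Linear-scale perturbagen expression (genes by samples) with per-sample
#' metadata, held as a [SummarizedExperiment::SummarizedExperiment].
#'
#' @param values genes-by-samples matrix of positive linear-scale expression.
#' @param metadata `data.frame` with columns `sample_id`, `drug_id`, `dose`,
#'   `time`, `replicate`, `is_control`, one row per matrix column.
#' @return A `SummarizedExperiment` with an `exprs` assay.
#' @export
perturbagen_set <- function(values, metadata) {
  required <- c("sample_id", "drug_id", "dose", "time", "replicate", "is_control")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop2("perturbagen metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(metadata) != ncol(values)) {
    stop2("metadata rows (", nrow(metadata), ") != matrix columns (", ncol(values), ")")
  }
  if (is.null(colnames(values))) colnames(values) <- metadata$sample_id
  if (!setequal(colnames(values), metadata$sample_id) || anyDuplicated(metadata$sample_id)) {
    stop2("sample ids in metadata must match matrix columns one-to-one")
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  if (!is.logical(metadata$is_control)) {
    stop2("is_control must be logical")
  }
  if (!any(metadata$is_control)) stop2("at least one control sample is required")
  if (all(metadata$is_control)) stop2("control samples must be a strict subset")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = as.matrix(values)),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id)
  )
}

#' Construct a gene-set collection
#'
#' @param terms named list of character vectors (term name -> member genes).
#' @param description optional named character vector of term descriptions.
#' @return A `gene_set_collection` object (named list with descriptions).
#' @export
gene_set_collection <- function(terms, description = NULL) {
  if (is.null(names(terms)) || any(names(terms) == "")) {
    stop2("every term needs a name")
  }
  if (anyDuplicated(names(terms))) stop2("duplicate term names")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- names(terms)[lengths(terms) == 0L]
  if (length(empty)) stop2("empty term(s): ", paste(empty, collapse = ", "))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(terms)), names(terms))
  }
  structure(list(terms = terms, description = description[names(terms)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x$terms), "terms; sizes",
      paste(range(lengths(x$terms)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$terms)

# Pull the counts / logcounts assay out of whatever the caller handed us.
get_assay <- function(x, name) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!name %in% SummarizedExperiment::assayNames(x)) {
      stop2("object has no '", name, "' assay; run the upstream step first")
    }
    SummarizedExperiment::assay(x, name)
  } else {
    x
  }
}
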