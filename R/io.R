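# Readers and writers for the pipeline's on-disk formats: MatrixMarket
# counts with gene/cell annotation TSVs (or a dense CSV), perturbagen
# CSV + metadata TSV, GMT gene sets, and plain TSV stage tables.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a labeled expression matrix
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv` (one gene per line) and
#' `cells.tsv` (columns `cell_id`, `condition`, `subtype`, `patient`) into
#' `dir`.
#'
#' @param m labeled expression matrix.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- get_assay(m, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  cells <- as.data.frame(SummarizedExperiment::colData(m))
  write_tsv(cells[, c("cell_id", "condition", "subtype", "patient")],
            file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a labeled expression matrix
#'
#' Accepts either the MTX triplet layout written by [write_expression()]
#' (`matrix.mtx` + `genes.tsv` + `cells.tsv` in a directory) or a dense CSV
#' (genes x cells, first column gene names) with a matching `cells.tsv`-style
#' annotation file. MatrixMarket 1-based indices are handled by the reader.
#'
#' @param path directory with the MTX triplet, or path to a dense CSV.
#' @param annotation path to the cell-annotation TSV (required for CSV input;
#'   defaults to `cells.tsv` next to the CSV).
#' @return A labeled expression matrix.
#' @export
read_expression <- function(path, annotation = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop2("no matrix.mtx under ", path)
    counts <- tryCatch(Matrix::readMM(mtx),
                       error = function(e) stop2("malformed MTX file ", mtx, ": ",
                                                 conditionMessage(e)))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- read_tsv(file.path(path, "cells.tsv"))
    if (length(genes) != nrow(counts)) {
      stop2("genes.tsv has ", length(genes), " entries but matrix has ",
            nrow(counts), " rows")
    }
    if (nrow(cells) != ncol(counts)) {
      stop2("cells.tsv has ", nrow(cells), " rows but matrix has ",
            ncol(counts), " columns")
    }
    rownames(counts) <- genes
    colnames(counts) <- cells$cell_id
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
    ann_path <- annotation %||% file.path(dirname(path), "cells.tsv")
    if (!file.exists(ann_path)) stop2("no cell annotation at ", ann_path)
    cells <- read_tsv(ann_path)
  }
  labeled_expression_matrix(counts, cells)
}

#' Write a perturbagen set
#'
#' Writes `perturbagens.csv` (genes x samples, first column `gene`) and
#' `perturbagen_meta.tsv` (columns `sample_id`, `drug_id`, `dose`, `time`,
#' `replicate`, `is_control`) into `dir`.
#'
#' @param p perturbagen set.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_perturbagens <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  values <- get_assay(p, "exprs")
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file.path(dir, "perturbagens.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(p))
  write_tsv(meta, file.path(dir, "perturbagen_meta.tsv"))
  invisible(dir)
}

#' Read a perturbagen set written by [write_perturbagens()]
#'
#' @param dir directory containing `perturbagens.csv` and
#'   `perturbagen_meta.tsv`.
#' @return A perturbagen set.
#' @export
read_perturbagens <- function(dir) {
  df <- utils::read.csv(file.path(dir, "perturbagens.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- read_tsv(file.path(dir, "perturbagen_meta.tsv"))
  meta$is_control <- as.logical(meta$is_control)
  perturbagen_set(values, meta)
}

#' Read a GMT gene-set file
#'
#' Tab-separated: term name, description, then member genes. Duplicate genes
#' within a term are removed; empty terms are rejected.
#'
#' @param path path to the GMT file.
#' @return A [gene_set_collection()]; empty files give an empty collection
#'   with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(terms = list(), description = character()),
                     class = "gene_set_collection"))
  }
  terms <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop2("GMT line ", i, " has fewer than 3 fields")
    }
    terms[[fields[1]]] <- unique(fields[-(1:2)])
    desc[fields[1]] <- fields[2]
  }
  gene_set_collection(terms, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(nm) {
    d <- unname(collection$description[nm])
    if (is.na(d)) d <- ""
    paste(c(nm, d, collection$terms[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
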