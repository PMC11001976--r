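# Correlation modules per candidate gene, hypergeometric gene-set enrichment,
# and guard-set derivation (genes a repositioned drug must not co-suppress,
# e.g. the MHC complex partners of B2M).

#' Extract each candidate's correlated-gene module
#'
#' Pearson correlation of every candidate against every other variable gene
#' across cells, with a two-sided p-value from the t-transform on `n - 2`
#' degrees of freedom and Bonferroni adjustment over the
#' `length(variable_genes) - 1` tests per candidate. Genes are retained when
#' `r > r_min` (signed, not absolute: the module captures co-upregulated
#' partners) and `padj < alpha`; the top `top_n` by descending `r` are kept,
#' ties broken by gene name.
#'
#' @param norm log-normalized expression (`SingleCellExperiment` with
#'   `logcounts`, or matrix).
#' @param variable_genes gene universe for the correlation (e.g. the top-3000
#'   variable genes).
#' @param candidates candidate genes (must be measured).
#' @param r_min signed correlation threshold (default 0.3).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param top_n module size cap (default 50).
#' @return Named list of `data.frame`s (one per candidate) with columns
#'   `gene`, `r`, `pvalue`, `padj`, `rank`; attribute `n_constant` counts
#'   skipped constant partner genes, attribute `flag` marks a zero-variance
#'   candidate.
#' @export
correlate_with_candidates <- function(norm, variable_genes, candidates,
                                      r_min = 0.3, alpha = 0.05, top_n = 50L) {
  x <- get_assay(norm, "logcounts")
  if (ncol(x) < 3L) stop2("at least 3 cells are required")
  assert_prob(alpha, "alpha")
  assert_count(top_n, "top_n")
  missing_cand <- setdiff(candidates, rownames(x))
  if (length(missing_cand)) {
    stop2("candidate(s) not measured: ", paste(missing_cand, collapse = ", "))
  }
  variable_genes <- intersect(variable_genes, rownames(x))
  n <- ncol(x)
  xv <- t(as.matrix(x[union(variable_genes, candidates), , drop = FALSE]))
  sds <- apply(xv, 2L, stats::sd)
  out <- list()
  for (cand in candidates) {
    partners <- setdiff(variable_genes, cand)
    m <- length(partners)
    if (sds[cand] == 0) {
      mod <- data.frame(gene = character(), r = numeric(), pvalue = numeric(),
                        padj = numeric(), rank = integer())
      attr(mod, "flag") <- "zero-variance candidate"
      attr(mod, "n_constant") <- 0L
      out[[cand]] <- mod
      next
    }
    usable <- partners[sds[partners] > 0]
    n_constant <- m - length(usable)
    r <- as.vector(stats::cor(xv[, cand], xv[, usable, drop = FALSE]))
    r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    padj <- pmin(1, p * m)  # Bonferroni over all partner tests per candidate
    keep <- r > r_min & padj < alpha
    mod <- data.frame(gene = usable[keep], r = r[keep], pvalue = p[keep],
                      padj = padj[keep], stringsAsFactors = FALSE)
    mod <- mod[order(-mod$r, mod$gene), , drop = FALSE]
    mod <- utils::head(mod, top_n)
    mod$rank <- seq_len(nrow(mod))
    rownames(mod) <- NULL
    attr(mod, "flag") <- "ok"
    attr(mod, "n_constant") <- n_constant
    out[[cand]] <- mod
  }
  out
}

#' Hypergeometric gene-set enrichment of a correlation module
#'
#' One-sided upper-tail hypergeometric test of the overlap between the module
#' genes and each term (both intersected with the universe of measured genes),
#' Benjamini-Hochberg adjustment across tested terms, and selection of the
#' significantly enriched terms sorted by ascending adjusted p.
#'
#' @param module a candidate's module `data.frame` (column `gene`), or a
#'   character vector of module genes.
#' @param collection a [gene_set_collection()].
#' @param universe measured-gene universe the module was drawn from.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param top_terms number of terms to report (default 5).
#' @return `data.frame` with columns `term`, `overlap`, `term_size`,
#'   `module_size`, `universe_size`, `pvalue`, `padj` (possibly zero rows).
#' @export
hypergeometric_enrichment <- function(module, collection, universe,
                                      alpha = 0.05, top_terms = 5L) {
  if (!length(universe)) stop2("empty universe")
  universe <- unique(as.character(universe))
  genes <- if (is.data.frame(module)) module$gene else as.character(module)
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    stop2("module gene(s) outside the universe: ", paste(outside, collapse = ", "))
  }
  empty <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), module_size = integer(),
                      universe_size = integer(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE)
  if (!length(genes)) return(empty)
  N <- length(universe)
  k <- length(genes)
  rows <- lapply(names(collection$terms), function(nm) {
    term_genes <- intersect(collection$terms[[nm]], universe)
    K <- length(term_genes)
    if (K == 0L) return(NULL)
    ov <- length(intersect(term_genes, genes))
    p <- stats::phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
    data.frame(term = nm, overlap = ov, term_size = K, module_size = k,
               universe_size = N, pvalue = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[res$padj < alpha, , drop = FALSE]
  res <- res[order(res$padj, res$pvalue, res$term), , drop = FALSE]
  res <- utils::head(res, top_terms)
  rownames(res) <- NULL
  res
}

#' Derive guard gene sets from enriched terms
#'
#' For each candidate, the guard set is the union of the member genes of its
#' enriched terms whose names match any of the supplied patterns (default
#' `"MHC"`), intersected with the measured genes and excluding the candidate
#' itself. A drug selected to suppress the candidate must not co-suppress its
#' guard genes.
#'
#' @param enrichments named list (candidate -> enrichment `data.frame` from
#'   [hypergeometric_enrichment()]).
#' @param collection the [gene_set_collection()] the terms came from.
#' @param guard_term_patterns character vector of regular expressions matched
#'   against enriched term names.
#' @param measured measured-gene universe.
#' @return Named list (candidate -> `list(guard_genes=, source_terms=)`).
#'   Empty (with a warning) when no pattern matches any enriched term.
#' @export
derive_guard_sets <- function(enrichments, collection,
                              guard_term_patterns = "MHC", measured) {
  if (!length(guard_term_patterns)) stop2("guard_term_patterns must be nonempty")
  out <- list()
  any_match <- FALSE
  for (cand in names(enrichments)) {
    enr <- enrichments[[cand]]
    if (is.null(enr) || !nrow(enr)) {
      out[[cand]] <- list(guard_genes = character(), source_terms = character())
      next
    }
    hits <- enr$term[Reduce(`|`, lapply(guard_term_patterns, grepl, x = enr$term))]
    genes <- unique(unlist(collection$terms[hits], use.names = FALSE))
    genes <- setdiff(intersect(genes, measured), cand)
    if (length(hits)) any_match <- TRUE
    out[[cand]] <- list(guard_genes = sort(genes), source_terms = hits)
  }
  if (!any_match) {
    warning("no enriched term matched any guard pattern for any candidate",
            call. = FALSE)
  }
  out
}
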