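# Panel differential expression: two-part hurdle test with a patient
# covariate, direction calls, and derivation of the repositioning plan.

# Likelihood-ratio chi-square of a binomial GLM comparing full vs null design.
lrt_logistic <- function(y, x_full, x_null) {
  fit_full <- suppressWarnings(
    stats::glm.fit(x_full, y, family = stats::binomial()))
  fit_null <- suppressWarnings(
    stats::glm.fit(x_null, y, family = stats::binomial()))
  df <- fit_full$rank - fit_null$rank
  if (df <= 0) return(c(stat = 0, df = 0))
  c(stat = max(0, fit_null$deviance - fit_full$deviance), df = df)
}

# Gaussian LRT (MLE variance): n * log(RSS0 / RSS1).
lrt_gaussian <- function(y, x_full, x_null) {
  fit_full <- stats::lm.fit(x_full, y)
  fit_null <- stats::lm.fit(x_null, y)
  df <- fit_full$rank - fit_null$rank
  rss1 <- sum(fit_full$residuals^2)
  rss0 <- sum(fit_null$residuals^2)
  if (df <= 0 || rss1 <= .Machine$double.eps * length(y)) {
    return(c(stat = 0, df = 0))
  }
  c(stat = max(0, length(y) * log(rss0 / rss1)), df = df)
}

#' Two-part hurdle differential-expression test
#'
#' For each gene, combines (1) a detection component — a logistic
#' likelihood-ratio test of the group effect on `value > 0` — with (2) a
#' continuous component — a Gaussian likelihood-ratio test of the group
#' effect on the positive log-normalized values. The patient label enters both
#' components as a fixed-effect covariate. Component chi-square statistics and
#' degrees of freedom are summed; the combined statistic is referred to a
#' chi-square distribution. The test reduces to its continuous component when
#' no zeros exist and to its detection component when all positive values are
#' tied.
#'
#' The reported effect size is
#' `lfc = log2((mean(expm1(norm_A)) + eps) / (mean(expm1(norm_B)) + eps))`,
#' with pseudocount `eps` defaulting to 1 / (size of the smaller group).
#'
#' @param norm log-normalized expression (a `SingleCellExperiment` carrying a
#'   `logcounts` assay, or a bare matrix).
#' @param cells_a,cells_b disjoint cell-id vectors defining the contrast
#'   (group A vs group B, e.g. one malignant subtype vs normal).
#' @param patient per-cell covariate; taken from `colData(norm)$patient` when
#'   `NULL` and available. If any patient level lies entirely within one
#'   group the covariate is dropped for the contrast, with a warning.
#' @param genes genes to test (default: all).
#' @param eps pseudocount for the fold-change ratio.
#' @return `data.frame` with columns `gene`, `lfc`, `pvalue`, `flag`
#'   (`"ok"` or `"undetected"`).
#' @export
hurdle_deg_test <- function(norm, cells_a, cells_b, patient = NULL,
                            genes = NULL, eps = NULL) {
  x <- get_assay(norm, "logcounts")
  if (!length(cells_a) || !length(cells_b)) stop2("both groups must be nonempty")
  if (length(intersect(cells_a, cells_b))) {
    stop2("cells appear in both groups: ",
          paste(utils::head(intersect(cells_a, cells_b), 5L), collapse = ", "))
  }
  missing_cells <- setdiff(c(cells_a, cells_b), colnames(x))
  if (length(missing_cells)) {
    stop2("unknown cell id(s): ", paste(utils::head(missing_cells, 5L), collapse = ", "))
  }
  if (is.null(patient) && methods::is(norm, "SummarizedExperiment")) {
    patient <- stats::setNames(SummarizedExperiment::colData(norm)$patient,
                               colnames(norm))
  }
  cells <- c(cells_a, cells_b)
  group <- factor(rep(c("A", "B"), c(length(cells_a), length(cells_b))),
                  levels = c("B", "A"))
  x <- x[, cells, drop = FALSE]
  if (is.null(genes)) genes <- rownames(x)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes)) {
    stop2("gene(s) not in matrix: ", paste(utils::head(missing_genes, 5L), collapse = ", "))
  }

  use_covariate <- FALSE
  if (!is.null(patient)) {
    pat <- factor(patient[cells])
    tab <- table(pat, group)
    exclusive <- rowSums(tab > 0) < 2L
    if (any(exclusive)) {
      warning("patient level(s) entirely within one group (",
              paste(utils::head(rownames(tab)[exclusive], 5L), collapse = ", "),
              "); dropping the patient covariate for this contrast",
              call. = FALSE)
    } else if (nlevels(pat) > 1L) {
      use_covariate <- TRUE
    }
  }
  if (use_covariate) {
    x_full <- stats::model.matrix(~ group + pat)
    x_null <- stats::model.matrix(~ pat)
  } else {
    x_full <- stats::model.matrix(~ group)
    x_null <- matrix(1, nrow = length(cells), ncol = 1L)
  }
  in_a <- seq_along(cells_a)
  eps <- eps %||% (1 / min(length(cells_a), length(cells_b)))

  res <- data.frame(gene = genes, lfc = 0, pvalue = 1, flag = "ok",
                    stringsAsFactors = FALSE)
  xm <- as.matrix(x[genes, , drop = FALSE])
  for (k in seq_along(genes)) {
    y <- xm[k, ]
    det <- y > 0
    if (!any(det)) {
      res$flag[k] <- "undetected"
      next
    }
    res$lfc[k] <- log2((mean(expm1(y[in_a])) + eps) /
                       (mean(expm1(y[-in_a])) + eps))
    stat <- 0
    df <- 0
    if (any(det) && !all(det)) {
      l <- lrt_logistic(as.numeric(det), x_full, x_null)
      stat <- stat + l["stat"]; df <- df + l["df"]
    }
    if (sum(det) > ncol(x_full)) {
      g <- lrt_gaussian(y[det], x_full[det, , drop = FALSE],
                        x_null[det, , drop = FALSE])
      stat <- stat + g["stat"]; df <- df + g["df"]
    }
    res$pvalue[k] <- if (df > 0) {
      stats::pchisq(stat, df = df, lower.tail = FALSE)
    } else 1
  }
  res
}

#' Call per-gene deregulation directions with multiple-testing correction
#'
#' Adjusts p-values across the tested panel within each contrast and calls
#' `up` when `padj < alpha` and `lfc >= lfc_min`, `down` when `padj < alpha`
#' and `lfc <= -lfc_min`, otherwise `ns`. The significance boundary uses a
#' strict inequality: `padj` exactly equal to `alpha` is `ns`.
#'
#' @param records `data.frame` with columns `gene`, `contrast`, `lfc`,
#'   `pvalue` (one row per gene x contrast; output of [hurdle_deg_test()]
#'   with a `contrast` column added).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param lfc_min minimum absolute log2 fold change; default 0.25.
#' @param mt_method `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return The input with `padj` and `direction` columns added.
#' @export
classify_deregulation <- function(records, alpha = 0.05, lfc_min = 0.25,
                                  mt_method = c("bh", "bonferroni")) {
  mt_method <- match.arg(mt_method)
  if (is.null(records) || !nrow(records)) stop2("empty record set")
  if (!all(c("gene", "contrast", "lfc", "pvalue") %in% names(records))) {
    stop2("records need columns gene, contrast, lfc, pvalue")
  }
  if (alpha <= 0 || alpha >= 1) stop2("alpha must lie in (0, 1)")
  assert_nonnegative(lfc_min, "lfc_min")
  method <- c(bh = "BH", bonferroni = "bonferroni")[[mt_method]]
  records$padj <- stats::ave(records$pvalue, records$contrast,
                             FUN = function(p) stats::p.adjust(p, method = method))
  records$direction <- ifelse(
    records$padj < alpha & records$lfc >= lfc_min, "up",
    ifelse(records$padj < alpha & records$lfc <= -lfc_min, "down", "ns"))
  records
}

#' Read a panel annotation table
#'
#' Tab-separated file with header `gene`, `role` (or `therapeutic_role`) and
#' `dr_direction` in \{Up, Down, None\} — the per-gene therapeutic role and
#' desired repositioning plane.
#'
#' @param path path to the TSV.
#' @return `data.frame` with columns `gene`, `therapeutic_role`,
#'   `dr_direction`.
#' @export
read_panel_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("role" %in% names(ann) && !"therapeutic_role" %in% names(ann)) {
    names(ann)[names(ann) == "role"] <- "therapeutic_role"
  }
  need <- c("gene", "therapeutic_role", "dr_direction")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop2("panel annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$gene)) {
    stop2("duplicate gene(s) in panel annotation: ",
          paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  }
  bad <- setdiff(unique(ann$dr_direction), c("Up", "Down", "None"))
  if (length(bad)) {
    stop2("dr_direction must be Up, Down or None; found: ", paste(bad, collapse = ", "))
  }
  ann[, need]
}

#' Build the drug-repositioning plan from panel annotation and DEG calls
#'
#' A gene enters the plan on its annotated plane only when the observed calls
#' are consistent with it: an Up-plane gene must be called `down` or `ns` in
#' at least one contrast (it is a gene worth restoring), while a Down-plane
#' gene must be called `up` in at least one contrast (it is an overexpressed
#' target worth suppressing). Genes annotated `None` never enter the plan.
#'
#' @param panel panel annotation (see [read_panel_annotation()]).
#' @param deg classified DEG records (see [classify_deregulation()]).
#' @return `data.frame` with columns `gene`, `plane`, `provenance`,
#'   `therapeutic_role` — the repositioning plan.
#' @export
build_reposition_plan <- function(panel, deg) {
  if (!all(c("gene", "dr_direction") %in% names(panel))) {
    stop2("panel needs columns gene and dr_direction")
  }
  if (!all(c("gene", "contrast", "direction") %in% names(deg))) {
    stop2("deg needs columns gene, contrast, direction")
  }
  uncovered <- setdiff(panel$gene, deg$gene)
  if (length(uncovered)) {
    stop2("DEG records cover no contrast for panel gene(s): ",
          paste(uncovered, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    plane <- panel$dr_direction[i]
    if (plane == "None") next
    g <- panel$gene[i]
    calls <- deg[deg$gene == g, , drop = FALSE]
    support <- if (plane == "Up") {
      calls$contrast[calls$direction %in% c("down", "ns")]
    } else {
      calls$contrast[calls$direction == "up"]
    }
    if (length(support)) {
      rows[[g]] <- data.frame(
        gene = g, plane = plane,
        provenance = paste(support, collapse = ";"),
        therapeutic_role = if ("therapeutic_role" %in% names(panel))
          panel$therapeutic_role[i] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop2("no actionable targets")
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  plan
}
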