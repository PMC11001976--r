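# Perturbagen scoring: replicate-aggregated log2 fold changes versus DMSO,
# directional per-target ranking, contradictory-impact filtering across the
# plan, and guard-conflict reporting.

#' Filter perturbagen samples by dose and treatment duration
#'
#' Retains treatment samples matching the requested dose and time, plus
#' control (DMSO) samples matching the same criteria. Drugs whose replicates
#' all fail the filter are listed in a dropped-drugs report.
#'
#' @param p a perturbagen set (see [perturbagen_set()]).
#' @param dose,time metadata labels to match (e.g. `"10 uM"`, `"24 h"`).
#' @return The subset perturbagen set, with attributes `counts_per_drug`
#'   (kept replicate counts) and `dropped_drugs`.
#' @export
filter_perturbagens <- function(p, dose = "10 uM", time = "24 h") {
  meta <- as.data.frame(SummarizedExperiment::colData(p))
  keep <- meta$dose == dose & meta$time == time
  if (!any(keep & !meta$is_control)) {
    stop2("no treatment samples match dose '", dose, "' and time '", time, "'")
  }
  if (!any(keep & meta$is_control)) {
    stop2("no control samples match dose '", dose, "' and time '", time, "'")
  }
  all_drugs <- unique(meta$drug_id[!meta$is_control])
  kept_drugs <- unique(meta$drug_id[keep & !meta$is_control])
  out <- p[, keep]
  attr(out, "counts_per_drug") <- table(meta$drug_id[keep & !meta$is_control])
  attr(out, "dropped_drugs") <- setdiff(all_drugs, kept_drugs)
  out
}

#' Compute the drug-by-gene log2 fold-change matrix
#'
#' Replicate aggregation happens on the linear scale first:
#' `lfc(g, d) = log2(mean over d's replicates + pseudocount) -
#' log2(mean over control samples + pseudocount)` — log2-of-mean, not
#' mean-of-log2.
#'
#' @param p a (filtered) perturbagen set with linear-scale values.
#' @param pseudocount nonnegative constant added to both means (default 0;
#'   required positive when any mean is zero).
#' @return Matrix of log2 fold changes, genes x drugs (controls excluded).
#' @export
compute_drug_lfc <- function(p, pseudocount = 0) {
  assert_nonnegative(pseudocount, "pseudocount")
  values <- get_assay(p, "exprs")
  meta <- as.data.frame(SummarizedExperiment::colData(p))
  ctrl <- meta$is_control
  if (!any(ctrl)) stop2("no control samples after filtering")
  ctrl_mean <- rowMeans(values[, ctrl, drop = FALSE]) + pseudocount
  drugs <- sort(unique(meta$drug_id[!ctrl]))
  cols <- lapply(drugs, function(d) {
    sel <- meta$drug_id == d & !ctrl
    trt_mean <- rowMeans(values[, sel, drop = FALSE]) + pseudocount
    if (any(trt_mean == 0) || any(ctrl_mean == 0)) {
      stop2("zero replicate mean encountered; supply a positive pseudocount")
    }
    log2(trt_mean) - log2(ctrl_mean)
  })
  lfc <- matrix(unlist(cols), nrow = nrow(values),
                dimnames = list(rownames(values), drugs))
  lfc
}

#' Rank drugs for one target gene along its repositioning plane
#'
#' Up-plane targets sort by log2 fold change descending (drugs that raise the
#' gene first); Down-plane targets ascending. Ties break lexicographically by
#' drug id.
#'
#' @param lfc genes-x-drugs matrix from [compute_drug_lfc()].
#' @param gene target gene name.
#' @param plane `"Up"` or `"Down"`.
#' @param k number of drugs to return (default 50).
#' @return `data.frame` with columns `drug_id`, `target_gene`, `plane`,
#'   `target_lfc`, `rank`.
#' @export
rank_drugs_for_gene <- function(lfc, gene, plane = c("Up", "Down"), k = 50L) {
  plane <- match.arg(plane)
  assert_count(k, "k")
  if (!gene %in% rownames(lfc)) {
    near <- utils::head(agrep(gene, rownames(lfc), value = TRUE,
                              max.distance = 0.2), 5L)
    stop2("gene '", gene, "' not in LFC matrix",
          if (length(near)) paste0("; nearest matches: ", paste(near, collapse = ", ")))
  }
  v <- lfc[gene, ]
  ord <- if (plane == "Up") order(-v, colnames(lfc)) else order(v, colnames(lfc))
  ord <- utils::head(ord, k)
  data.frame(drug_id = colnames(lfc)[ord], target_gene = gene, plane = plane,
             target_lfc = unname(v[ord]), rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Score a drug's anti-plan movement across the rest of the panel
#'
#' For each plan gene other than the excluded target, movement against its
#' plane contributes its magnitude:
#' `score = sum over g of max(0, s(g) * (-lfc(g, drug)))` with `s(g) = +1`
#' for Up-plane and `-1` for Down-plane genes. Zero means the drug compromises
#' no other target.
#'
#' @param drug drug id (column of `lfc`).
#' @param plan repositioning plan (see [build_reposition_plan()]).
#' @param lfc genes-x-drugs LFC matrix.
#' @param exclude the target gene being evaluated (excluded from the sum).
#' @return Nonnegative conflict score; attribute `conflicting_genes` lists the
#'   plan genes that moved against their plane.
#' @export
panel_conflict_score <- function(drug, plan, lfc, exclude = NULL) {
  genes <- setdiff(plan$gene, exclude)
  missing_genes <- setdiff(genes, rownames(lfc))
  if (length(missing_genes)) {
    stop2("plan gene(s) not in LFC matrix: ", paste(missing_genes, collapse = ", "))
  }
  if (!drug %in% colnames(lfc)) stop2("drug '", drug, "' not in LFC matrix")
  if (!length(genes)) {
    score <- 0
    attr(score, "conflicting_genes") <- character()
    return(score)
  }
  s <- ifelse(plan$plane[match(genes, plan$gene)] == "Up", 1, -1)
  contrib <- pmax(0, s * (-lfc[genes, drug]))
  score <- sum(contrib)
  attr(score, "conflicting_genes") <- genes[contrib > 0]
  score
}

#' Filter ranked drugs with contradictory impacts across the plan
#'
#' A ranked (drug, target) row is excluded when its panel conflict score
#' exceeds `tau`; survivors are re-ranked within each target. Both kept and
#' excluded rows are emitted, with exclusion reasons naming the compromised
#' genes.
#'
#' @param ranked `data.frame` of per-target rankings (rows of
#'   [rank_drugs_for_gene()] stacked).
#' @param plan repositioning plan.
#' @param lfc genes-x-drugs LFC matrix.
#' @param tau conflict tolerance (default 0: strict sign-based exclusion).
#' @return Drug-candidate table: the input plus `panel_conflict`, `excluded`,
#'   `exclusion_reason`, re-ranked `rank` for survivors.
#' @export
filter_contradictory <- function(ranked, plan, lfc, tau = 0) {
  assert_nonnegative(tau, "tau")
  if (!nrow(ranked)) stop2("empty ranking")
  n <- nrow(ranked)
  ranked$panel_conflict <- NA_real_
  ranked$excluded <- FALSE
  ranked$exclusion_reason <- ""
  for (i in seq_len(n)) {
    sc <- panel_conflict_score(ranked$drug_id[i], plan, lfc,
                               exclude = ranked$target_gene[i])
    ranked$panel_conflict[i] <- as.numeric(sc)
    if (as.numeric(sc) > tau) {
      ranked$excluded[i] <- TRUE
      ranked$exclusion_reason[i] <- paste0(
        "anti-plan movement on ",
        paste(attr(sc, "conflicting_genes"), collapse = ","))
    }
  }
  parts <- split(ranked, ranked$target_gene)
  parts <- lapply(parts, function(df) {
    df <- df[order(df$rank), , drop = FALSE]
    df$rank[!df$excluded] <- seq_len(sum(!df$excluded))
    df$rank[df$excluded] <- NA_integer_
    if (!any(!df$excluded)) {
      warning("no candidate survives tau for target ", df$target_gene[1],
              call. = FALSE)
    }
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Score drug conflicts against guard gene sets and flag recommendations
#'
#' For each candidate row whose target carries a guard set (typically the
#' Down-plane targets correlated with MHC-complex genes), the guard conflict
#' is the total downregulation inflicted on guard genes:
#' `sum over guard genes h of max(0, -lfc(h, drug))`. Per guarded target, the
#' surviving drug with minimal guard conflict is flagged `recommended` (ties:
#' larger absolute target LFC, then drug id).
#'
#' @param candidates drug-candidate table from [filter_contradictory()].
#' @param guards named list (target gene -> guard set) from
#'   [derive_guard_sets()].
#' @param lfc genes-x-drugs LFC matrix.
#' @return `list(candidates=, detail=)`: the table with `guard_conflict` and
#'   `recommended` filled, and a per-(drug, guard gene) LFC detail table.
#' @export
guard_conflict_report <- function(candidates, guards, lfc) {
  candidates$guard_conflict <- 0
  candidates$recommended <- FALSE
  detail <- list()
  for (i in seq_len(nrow(candidates))) {
    target <- candidates$target_gene[i]
    gset <- guards[[target]]
    gg <- intersect(gset$guard_genes %||% character(), rownames(lfc))
    if (!length(gg)) next
    v <- lfc[gg, candidates$drug_id[i]]
    candidates$guard_conflict[i] <- sum(pmax(0, -v))
    detail[[length(detail) + 1L]] <- data.frame(
      drug_id = candidates$drug_id[i], target_gene = target, guard_gene = gg,
      lfc = unname(v), stringsAsFactors = FALSE)
  }
  for (target in unique(candidates$target_gene)) {
    gset <- guards[[target]]
    if (is.null(gset)) next
    sel <- which(candidates$target_gene == target & !candidates$excluded)
    if (!length(sel)) next
    df <- candidates[sel, ]
    ord <- order(df$guard_conflict, -abs(df$target_lfc), df$drug_id)
    candidates$recommended[sel[ord[1L]]] <- TRUE
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(drug_id = character(), target_gene = character(),
               guard_gene = character(), lfc = numeric(),
               stringsAsFactors = FALSE)
  list(candidates = candidates, detail = detail)
}
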