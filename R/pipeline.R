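# Pipeline configuration and end-to-end orchestration:
# simulate -> deg -> correlate -> enrich -> reposition.

#' Default planted perturbagen effects for the bundled fixture
#'
#' One "clean" drug per plan target moving it along its plane, plus a "dirty"
#' B2M drug that also suppresses the MHC guard genes — the constructed pair
#' that the guard-conflict stage must tell apart. The clean suppressors are
#' modeled as MHC-sparing (mildly inducing the antigen-presentation genes),
#' the profile the guard logic is meant to reward.
#'
#' @return Named list, drug id -> named numeric vector of log2 effects.
#' @export
default_planted_drug_effects <- function() {
  hla_spare <- c(`HLA-A` = 0.3, `HLA-B` = 0.3, `HLA-C` = 0.3, `HLA-DMA` = 0.3,
                 `HLA-DRA` = 0.3, `HLA-DRB1` = 0.3, TAP1 = 0.3)
  list(
    CLEAN_B2M  = c(c(B2M = -1.2), hla_spare),
    DIRTY_B2M  = c(B2M = -1.2, `HLA-A` = -1, `HLA-B` = -1, `HLA-DMA` = -1),
    CLEAN_SLPI = c(c(SLPI = -1.2), hla_spare),
    UP_PIGR    = c(PIGR = 1.2),
    UP_DEFB1   = c(DEFB1 = 1.2),
    UP_LTF     = c(LTF = 1.2),
    UP_CLU     = c(CLU = 1.2),
    UP_S100A7  = c(S100A7 = 1.2),
    UP_SCGB2A1 = c(SCGB2A1 = 1.2)
  )
}

#' Build a pipeline configuration
#'
#' Collects all stage parameters, paths and the master seed. Defaults define
#' the bundled synthetic study: a two-condition multi-patient count matrix
#' with planted panel-gene effects and an MHC-like co-expression module
#' around B2M, plus a DMSO-controlled perturbagen panel with planted clean
#' and dirty drugs.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed master seed; each stage derives a sub-seed via [derive_seed()].
#' @param alpha,lfc_min,mt_method DEG call parameters.
#' @param scale_factor log-normalization constant.
#' @param n_variable number of variable genes for the correlation stage.
#' @param r_min,top_n correlation module parameters.
#' @param top_terms,guard_term_patterns enrichment / guard parameters.
#' @param k,tau,dose,time,pseudocount repositioning parameters.
#' @param panel_annotation path to the panel annotation TSV (default: the
#'   bundled table).
#' @param gmt optional path to a GMT file; when `NULL` the gene-set generator
#'   supplies a collection with a planted MHC term.
#' @param sc_sim,perturb_sim,gene_sets optional overrides (lists of arguments
#'   to [sc_sim_config()], [perturb_sim_config()], [gene_set_sim_config()]).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            alpha = 0.05, lfc_min = 0.25, mt_method = "bh",
                            scale_factor = 1e4, n_variable = 300L,
                            r_min = 0.3, top_n = 50L,
                            top_terms = 5L, guard_term_patterns = "MHC",
                            k = 50L, tau = 0.5, dose = "10 uM", time = "24 h",
                            pseudocount = 0,
                            panel_annotation = NULL, gmt = NULL,
                            sc_sim = list(), perturb_sim = list(),
                            gene_sets = list()) {
  cfg <- list(out_dir = out_dir, seed = assert_count(seed, "seed", min = 0L),
              alpha = alpha, lfc_min = lfc_min, mt_method = mt_method,
              scale_factor = scale_factor, n_variable = n_variable,
              r_min = r_min, top_n = top_n, top_terms = top_terms,
              guard_term_patterns = guard_term_patterns,
              k = k, tau = tau, dose = dose, time = time,
              pseudocount = pseudocount,
              panel_annotation = panel_annotation, gmt = gmt,
              sc_sim = sc_sim, perturb_sim = perturb_sim,
              gene_sets = gene_sets)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Range-checks every threshold before any stage runs.
#'
#' @param cfg a `pipeline_config`.
#' @return `cfg`, invisibly; errors on the first violated range.
#' @export
validate_pipeline_config <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop2("alpha must lie in (0, 1)")
  assert_nonnegative(cfg$lfc_min, "lfc_min")
  if (!cfg$mt_method %in% c("bh", "bonferroni")) {
    stop2("mt_method must be 'bh' or 'bonferroni'")
  }
  assert_positive(cfg$scale_factor, "scale_factor")
  assert_count(cfg$n_variable, "n_variable")
  if (!is.numeric(cfg$r_min) || cfg$r_min < -1 || cfg$r_min > 1) {
    stop2("r_min must lie in [-1, 1]")
  }
  assert_count(cfg$top_n, "top_n")
  assert_count(cfg$top_terms, "top_terms")
  if (!length(cfg$guard_term_patterns)) stop2("guard_term_patterns must be nonempty")
  assert_count(cfg$k, "k")
  assert_nonnegative(cfg$tau, "tau")
  assert_nonnegative(cfg$pseudocount, "pseudocount")
  invisible(cfg)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' One nesting level is allowed (the `sc_sim`, `perturb_sim` and `gene_sets`
#' blocks); unknown keys are errors.
#'
#' @param path path to the YAML file.
#' @param out_dir output directory (overrides any `out_dir` key).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), character())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (is.null(raw$out_dir)) stop2("config must set out_dir")
  do.call(pipeline_config, raw)
}

default_sc_sim_args <- function(seed) {
  hla <- c("HLA-A", "HLA-B", "HLA-C", "HLA-DMA", "HLA-DRA", "HLA-DRB1", "TAP1")
  list(
    n_genes = 600L, n_cells_per_group = 400L, n_patients_per_group = 3L,
    panel_genes = c("B2M", "SLPI", "PIGR", "DEFB1", "LTF", "CLU", "S100A7",
                    "SCGB2A1", "BST2", "CCL20", "GAPDH", hla),
    planted_lfc = c(B2M = 1.5, SLPI = 1.5, PIGR = -1.5, DEFB1 = -1.5,
                    LTF = -1.5, CLU = -1.5, BST2 = 1, CCL20 = 1),
    base_mean = 2, dispersion = 2, dropout_rate = 0.1, batch_sd = 0.1,
    coexpr = list(anchor = "B2M", partners = c(hla, "SLPI"), strength = 2,
                  base_mean = 25),
    seed = seed)
}

default_gene_set_args <- function(seed) {
  list(n_terms = 15L, term_size_range = c(5L, 40L),
       planted_term = list(
         name = "MHC_PROTEIN_COMPLEX",
         genes = c("B2M", "HLA-A", "HLA-B", "HLA-C", "HLA-DMA", "HLA-DRA",
                   "HLA-DRB1", "TAP1")),
       seed = seed)
}

default_perturb_sim_args <- function(seed, gene_names) {
  list(n_genes = length(gene_names), gene_names = gene_names, n_drugs = 50L,
       n_reps = 3L, n_control_reps = 6L,
       planted_effects = default_planted_drug_effects(),
       noise_sd = 0.1, baseline_mean = 100, seed = seed)
}

#' Run the full pipeline on a configuration
#'
#' Executes simulate -> normalize/variable genes -> hurdle DEG per
#' subtype-vs-normal contrast -> direction calls -> repositioning plan ->
#' correlation modules -> enrichment -> guard sets -> perturbagen LFC ->
#' directional ranking -> contradictory-impact filter -> guard-conflict
#' report, writing every stage artifact plus a manifest of parameters and
#' output hashes. Rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, `list(status = 0, manifest = <data.frame>, ...)` with
#'   the in-memory stage results.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[amp-reposition] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # --- simulate -------------------------------------------------------------
  sc_args <- utils::modifyList(default_sc_sim_args(derive_seed(cfg$seed, 1L)),
                               cfg$sc_sim)
  say("simulating single-cell counts (", sc_args$n_genes, " genes x 2 x ",
      sc_args$n_cells_per_group, " cells)")
  m <- stage("simulate", {
    sc <- do.call(sc_sim_config, sc_args)
    simulate_sc_counts(sc)
  })
  write_expression(m, file.path(cfg$out_dir, "expression"))

  # --- deg ------------------------------------------------------------------
  say("normalizing and testing the panel")
  panel_path <- cfg$panel_annotation %||%
    system.file("extdata", "panel_annotation.tsv", package = "ampReposition")
  panel <- read_panel_annotation(panel_path)
  deg_out <- stage("deg", {
    norm <- log_normalize(m, cfg$scale_factor)
    n_var <- min(cfg$n_variable, nrow(norm))
    variable_genes <- select_variable_genes(norm, n_top = n_var)
    cd <- as.data.frame(SummarizedExperiment::colData(norm))
    panel_genes <- intersect(panel$gene, rownames(norm))
    normal_cells <- cd$cell_id[cd$condition == "normal"]
    recs <- list()
    for (st in sort(unique(cd$subtype[cd$condition == "malignant"]))) {
      mal_cells <- cd$cell_id[cd$condition == "malignant" & cd$subtype == st]
      r <- suppressWarnings(
        hurdle_deg_test(norm, mal_cells, normal_cells, genes = panel_genes))
      r$contrast <- paste0(st, "_vs_normal")
      recs[[st]] <- r
    }
    deg <- classify_deregulation(do.call(rbind, recs), alpha = cfg$alpha,
                                 lfc_min = cfg$lfc_min,
                                 mt_method = cfg$mt_method)
    list(norm = norm, variable_genes = variable_genes, deg = deg)
  })
  deg <- deg_out$deg
  rownames(deg) <- NULL
  write_tsv(deg[, c("gene", "contrast", "lfc", "pvalue", "padj", "direction")],
            file.path(cfg$out_dir, "deg.tsv"))

  # --- plan -----------------------------------------------------------------
  panel_measured <- panel[panel$gene %in% rownames(deg_out$norm), , drop = FALSE]
  unmeasured <- setdiff(panel$gene, panel_measured$gene)
  if (length(unmeasured)) {
    say("panel gene(s) not measured, skipped: ", paste(unmeasured, collapse = ", "))
  }
  plan <- stage("plan", build_reposition_plan(panel_measured, deg))
  write_tsv(plan, file.path(cfg$out_dir, "plan.tsv"))
  say("repositioning plan: ", paste(plan$gene, plan$plane, collapse = ", "))

  # --- correlate ------------------------------------------------------------
  say("extracting correlation modules")
  modules <- stage("correlate", correlate_with_candidates(
    deg_out$norm, deg_out$variable_genes, candidates = plan$gene,
    r_min = cfg$r_min, alpha = cfg$alpha, top_n = cfg$top_n))
  mod_rows <- do.call(rbind, lapply(names(modules), function(cand) {
    mod <- modules[[cand]]
    if (!nrow(mod)) return(NULL)
    cbind(candidate = cand, mod)
  }))
  if (is.null(mod_rows)) {
    mod_rows <- data.frame(candidate = character(), gene = character(),
                           r = numeric(), pvalue = numeric(), padj = numeric(),
                           rank = integer())
  }
  write_tsv(mod_rows, file.path(cfg$out_dir, "modules.tsv"))

  # --- enrich + guards ------------------------------------------------------
  say("testing enrichment and deriving guard sets")
  universe <- rownames(deg_out$norm)
  collection <- stage("enrich", {
    if (!is.null(cfg$gmt)) {
      read_gmt(cfg$gmt)
    } else {
      gs_args <- utils::modifyList(default_gene_set_args(derive_seed(cfg$seed, 2L)),
                                   cfg$gene_sets)
      make_gene_sets(do.call(gene_set_sim_config, gs_args), universe)
    }
  })
  write_gmt(collection, file.path(cfg$out_dir, "gene_sets.gmt"))
  enrichments <- stage("enrich", {
    lapply(modules, hypergeometric_enrichment, collection = collection,
           universe = universe, alpha = cfg$alpha, top_terms = cfg$top_terms)
  })
  enr_rows <- do.call(rbind, lapply(names(enrichments), function(cand) {
    e <- enrichments[[cand]]
    if (!nrow(e)) return(NULL)
    cbind(candidate = cand, e)
  }))
  if (is.null(enr_rows)) {
    enr_rows <- data.frame(candidate = character(), term = character(),
                           overlap = integer(), term_size = integer(),
                           module_size = integer(), universe_size = integer(),
                           pvalue = numeric(), padj = numeric())
  }
  write_tsv(enr_rows, file.path(cfg$out_dir, "enrichment.tsv"))
  guards <- stage("guards", suppressWarnings(derive_guard_sets(
    enrichments, collection, cfg$guard_term_patterns, measured = universe)))
  guard_rows <- do.call(rbind, lapply(names(guards), function(cand) {
    g <- guards[[cand]]
    if (!length(g$guard_genes)) return(NULL)
    data.frame(candidate = cand, guard_gene = g$guard_genes,
               source_term = paste(g$source_terms, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(guard_rows)) {
    guard_rows <- data.frame(candidate = character(), guard_gene = character(),
                             source_term = character())
  }
  write_tsv(guard_rows, file.path(cfg$out_dir, "guard.tsv"))

  # --- reposition -----------------------------------------------------------
  say("scoring perturbagens")
  pt_args <- utils::modifyList(
    default_perturb_sim_args(derive_seed(cfg$seed, 3L), universe),
    cfg$perturb_sim)
  result <- stage("reposition", {
    p <- simulate_perturbagen_panel(do.call(perturb_sim_config, pt_args))
    write_perturbagens(p, file.path(cfg$out_dir, "perturbagens"))
    pf <- filter_perturbagens(p, dose = cfg$dose, time = cfg$time)
    dropped <- attr(pf, "dropped_drugs")
    write_tsv(data.frame(drug_id = dropped %||% character()),
              file.path(cfg$out_dir, "dropped_drugs.tsv"))
    lfc <- compute_drug_lfc(pf, pseudocount = cfg$pseudocount)
    utils::write.csv(data.frame(gene = rownames(lfc), lfc, check.names = FALSE),
                     file.path(cfg$out_dir, "lfc_matrix.csv"), row.names = FALSE,
                     quote = FALSE)
    ranked <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
      rank_drugs_for_gene(lfc, plan$gene[i], plan$plane[i], k = cfg$k)
    }))
    table0 <- suppressWarnings(filter_contradictory(ranked, plan, lfc,
                                                    tau = cfg$tau))
    rep <- guard_conflict_report(table0, guards, lfc)
    list(lfc = lfc, candidates = rep$candidates, detail = rep$detail)
  })
  write_tsv(result$candidates, file.path(cfg$out_dir, "candidate_table.tsv"))
  write_tsv(result$detail, file.path(cfg$out_dir, "guard_detail.tsv"))

  # --- manifest -------------------------------------------------------------
  params <- cfg[c("seed", "alpha", "lfc_min", "mt_method", "scale_factor",
                  "n_variable", "r_min", "top_n", "top_terms", "k", "tau",
                  "dose", "time", "pseudocount")]
  say("parameters: ", paste(names(params), unlist(lapply(params, paste,
      collapse = ",")), sep = "=", collapse = " "))
  outputs <- c("deg.tsv", "plan.tsv", "modules.tsv", "enrichment.tsv",
               "guard.tsv", "gene_sets.gmt", "candidate_table.tsv",
               "guard_detail.tsv", "lfc_matrix.csv", "dropped_drugs.tsv",
               file.path("expression", c("matrix.mtx", "genes.tsv", "cells.tsv")),
               file.path("perturbagens", c("perturbagens.csv",
                                           "perturbagen_meta.tsv")))
  hashes <- tools::md5sum(file.path(cfg$out_dir, outputs))
  manifest <- rbind(
    data.frame(key = paste0("param:", names(params)),
               value = vapply(params, function(v) paste(v, collapse = ","),
                              character(1)),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("md5:", outputs), value = unname(hashes),
               stringsAsFactors = FALSE))
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(list(status = 0L, manifest = manifest, plan = plan,
                 candidates = result$candidates, guards = guards,
                 lfc = result$lfc, deg = deg))
}
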