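# Synthetic-data generators: every downstream stage is testable without any
# external download. The single-cell generator is a negative-binomial sampler
# with gene-level log-normal means, optional planted condition effects on
# panel genes, per-patient log-scale batch shifts, an optional latent-factor
# co-expression module, and independent Bernoulli dropout.

#' Configuration for the single-cell count simulator
#'
#' @param n_genes number of genes in the universe.
#' @param n_cells_per_group cells per condition (malignant / normal).
#' @param n_patients_per_group patients per condition; cells are split
#'   near-evenly across them.
#' @param panel_genes character vector of named panel genes inserted into the
#'   gene universe (they replace the first generic gene names).
#' @param planted_lfc named numeric vector, gene -> log2 effect applied to the
#'   malignant condition's expected expression (keys must be panel genes).
#' @param base_mean expected count scale; per-gene means are log-normal around
#'   it (sdlog 1).
#' @param dispersion negative-binomial size (shape) parameter.
#' @param dropout_rate probability that an observed count is zeroed,
#'   independently per entry.
#' @param batch_sd SD of the per-patient additive shift on the log mean.
#' @param coexpr optional planted co-expression module:
#'   `list(anchor=, partners=, strength=, base_mean=)`. A standard-normal
#'   latent factor per cell multiplies the expected expression of anchor and
#'   partners by `exp(strength * factor)`, inducing positive correlation among
#'   them. `base_mean` (optional) overrides the expected count of the module
#'   genes — antigen-presentation transcripts such as B2M/HLA are among the
#'   most abundant in epithelial cells, and a detectable module needs counts
#'   well above the dropout noise floor.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return A validated `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_genes = 1000L, n_cells_per_group = 500L,
                          n_patients_per_group = 4L,
                          panel_genes = character(), planted_lfc = numeric(),
                          base_mean = 2, dispersion = 2, dropout_rate = 0.1,
                          batch_sd = 0.1, coexpr = NULL, seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_cells_per_group, "n_cells_per_group")
  assert_count(n_patients_per_group, "n_patients_per_group")
  assert_positive(base_mean, "base_mean")
  assert_positive(dispersion, "dispersion")
  assert_prob(dropout_rate, "dropout_rate")
  assert_nonnegative(batch_sd, "batch_sd")
  assert_count(seed, "seed", min = 0L)
  panel_genes <- as.character(panel_genes)
  if (anyDuplicated(panel_genes)) stop2("field 'panel_genes' has duplicates")
  if (length(panel_genes) > n_genes) {
    stop2("field 'panel_genes' longer than n_genes")
  }
  if (length(planted_lfc)) {
    if (is.null(names(planted_lfc)) || any(names(planted_lfc) == "")) {
      stop2("field 'planted_lfc' must be a named vector")
    }
    outside <- setdiff(names(planted_lfc), panel_genes)
    if (length(outside)) {
      stop2("field 'planted_lfc' keys not in panel_genes: ",
            paste(outside, collapse = ", "))
    }
  }
  if (!is.null(coexpr)) {
    if (!all(c("anchor", "partners") %in% names(coexpr))) {
      stop2("field 'coexpr' needs elements 'anchor' and 'partners'")
    }
    coexpr$strength <- assert_nonnegative(coexpr$strength %||% 1, "coexpr$strength")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_group = as.integer(n_cells_per_group),
                 n_patients_per_group = as.integer(n_patients_per_group),
                 panel_genes = panel_genes,
                 planted_lfc = planted_lfc,
                 base_mean = base_mean, dispersion = dispersion,
                 dropout_rate = dropout_rate, batch_sd = batch_sd,
                 coexpr = coexpr, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate a two-condition multi-patient single-cell count matrix
#'
#' Genes in `planted_lfc` have their expected expression multiplied by
#' `2^planted_lfc` in the malignant condition before dropout. Malignant
#' patients are assigned breast-cancer subtypes (TNBC, ER+, HER2+) cyclically;
#' normal cells carry subtype `"none"`.
#'
#' @param cfg an [sc_sim_config()].
#' @return A labeled expression matrix (see [labeled_expression_matrix()]).
#' @export
simulate_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    if (length(cfg$panel_genes)) {
      genes[seq_along(cfg$panel_genes)] <- cfg$panel_genes
    }
    subtypes <- c("TNBC", "ER+", "HER2+")
    conds <- c("malignant", "normal")
    npat <- cfg$n_patients_per_group
    ncell <- cfg$n_cells_per_group

    # gene-level base means, shared by both conditions
    mu <- cfg$base_mean * stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    names(mu) <- genes

    cell_tabs <- list()
    blocks <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      pat_ids <- sprintf("%s_P%02d", ifelse(cond == "malignant", "BC", "N"),
                         seq_len(npat))
      pat_of_cell <- sort(rep(pat_ids, length.out = ncell))
      batch <- stats::rnorm(npat, 0, cfg$batch_sd)
      names(batch) <- pat_ids

      mu_cond <- mu
      if (cond == "malignant" && length(cfg$planted_lfc)) {
        mu_cond[names(cfg$planted_lfc)] <-
          mu_cond[names(cfg$planted_lfc)] * 2^unname(cfg$planted_lfc)
      }

      # expected value per (gene, cell): gene mean x patient shift x factor
      if (!is.null(cfg$coexpr) && !is.null(cfg$coexpr$base_mean)) {
        mod_genes <- intersect(c(cfg$coexpr$anchor, cfg$coexpr$partners), genes)
        scale_to <- cfg$coexpr$base_mean / mu[mod_genes]
        mu_cond[mod_genes] <- mu_cond[mod_genes] * scale_to
      }
      lam <- outer(mu_cond, exp(batch[pat_of_cell]))
      if (!is.null(cfg$coexpr)) {
        fac <- stats::rnorm(ncell)
        mod_genes <- intersect(c(cfg$coexpr$anchor, cfg$coexpr$partners), genes)
        lam[mod_genes, ] <- lam[mod_genes, , drop = FALSE] *
          matrix(exp(cfg$coexpr$strength * fac), nrow = length(mod_genes),
                 ncol = ncell, byrow = TRUE)
      }
      counts <- matrix(stats::rnbinom(length(lam), mu = lam, size = cfg$dispersion),
                       nrow = cfg$n_genes)
      if (cfg$dropout_rate > 0) {
        keep <- matrix(stats::rbinom(length(lam), 1L, 1 - cfg$dropout_rate),
                       nrow = cfg$n_genes)
        counts <- counts * keep
      }
      cell_ids <- sprintf("%s_C%05d", ifelse(cond == "malignant", "BC", "N"),
                          seq_len(ncell))
      dimnames(counts) <- list(genes, cell_ids)
      subtype <- if (cond == "malignant") {
        st_of_pat <- stats::setNames(rep(subtypes, length.out = npat), pat_ids)
        unname(st_of_pat[pat_of_cell])
      } else rep("none", ncell)
      cell_tabs[[ci]] <- data.frame(cell_id = cell_ids, condition = cond,
                                    subtype = subtype, patient = pat_of_cell,
                                    stringsAsFactors = FALSE)
      blocks[[ci]] <- counts
    }
    labeled_expression_matrix(do.call(cbind, blocks), do.call(rbind, cell_tabs))
  })
}

#' Configuration for the perturbagen panel simulator
#'
#' @param n_genes genes in the panel's measured universe.
#' @param n_drugs number of non-control drugs.
#' @param n_reps replicates per drug (>= 1).
#' @param n_control_reps DMSO control replicates (>= 2).
#' @param planted_effects named list, drug -> named numeric vector of per-gene
#'   log2 effects on expected expression.
#' @param noise_sd SD of log-scale multiplicative noise on linear values.
#' @param baseline_mean expected linear-scale expression of an unperturbed gene.
#' @param dose_label,time_label metadata labels stamped on every sample.
#' @param gene_names optional explicit gene universe (length `n_genes`), e.g.
#'   to share names with a single-cell matrix; default generic `G#####` names.
#' @param seed integer seed.
#' @return A validated `perturb_sim_config` list.
#' @export
perturb_sim_config <- function(n_genes = 200L, n_drugs = 50L, n_reps = 3L,
                               n_control_reps = 6L, planted_effects = list(),
                               noise_sd = 0.1, baseline_mean = 100,
                               dose_label = "10 uM", time_label = "24 h",
                               gene_names = NULL, seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_drugs, "n_drugs")
  assert_count(n_reps, "n_reps")
  n_control_reps <- assert_count(n_control_reps, "n_control_reps")
  if (n_control_reps < 2L) {
    stop2("field 'n_control_reps' must be >= 2 so the control mean is defined robustly")
  }
  assert_nonnegative(noise_sd, "noise_sd")
  assert_positive(baseline_mean, "baseline_mean")
  assert_count(seed, "seed", min = 0L)
  if (!is.null(gene_names)) {
    gene_names <- as.character(gene_names)
    if (length(gene_names) != n_genes) {
      stop2("field 'gene_names' must have length n_genes")
    }
    if (anyDuplicated(gene_names)) stop2("field 'gene_names' has duplicates")
  }
  genes <- gene_names %||% sprintf("G%05d", seq_len(n_genes))
  if (length(planted_effects)) {
    if (is.null(names(planted_effects))) stop2("field 'planted_effects' must be named by drug")
    for (d in names(planted_effects)) {
      eff <- planted_effects[[d]]
      if (is.null(names(eff))) stop2("planted effect for drug '", d, "' must be gene-named")
    }
  }
  structure(list(n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
                 n_reps = as.integer(n_reps),
                 n_control_reps = as.integer(n_control_reps),
                 planted_effects = planted_effects, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, dose_label = dose_label,
                 time_label = time_label, gene_names = gene_names,
                 seed = as.integer(seed)),
            class = "perturb_sim_config")
}

#' Simulate a DMSO-controlled perturbagen expression panel
#'
#' Linear-scale expression: drug `d`, gene `g` has expected value
#' `baseline_mean * 2^effect(d, g)` under log-normal multiplicative noise.
#' Exactly one control pseudo-drug labeled `DMSO` carries `is_control = TRUE`.
#'
#' @param cfg a [perturb_sim_config()].
#' @return A perturbagen set (see [perturbagen_set()]).
#' @export
simulate_perturbagen_panel <- function(cfg) {
  stopifnot(inherits(cfg, "perturb_sim_config"))
  with_seed(cfg$seed, {
    genes <- cfg$gene_names %||% sprintf("G%05d", seq_len(cfg$n_genes))
    drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
    planted <- cfg$planted_effects
    if (length(planted)) {
      unknown_drug <- setdiff(names(planted), drugs)
      # allow planting on drugs named outside the generic scheme by appending
      if (length(unknown_drug)) drugs <- c(drugs, unknown_drug)
      for (d in names(planted)) {
        outside <- setdiff(names(planted[[d]]), genes)
        if (length(outside)) {
          stop2("planted effect for drug '", d, "' names gene(s) outside the universe: ",
                paste(outside, collapse = ", "))
        }
      }
    }
    meta <- data.frame(
      sample_id = character(), drug_id = character(), dose = character(),
      time = character(), replicate = integer(), is_control = logical(),
      stringsAsFactors = FALSE)
    cols <- list()
    add_samples <- function(drug, nrep, is_control) {
      eff <- rep(0, length(genes))
      names(eff) <- genes
      if (!is_control && drug %in% names(planted)) {
        eff[names(planted[[drug]])] <- planted[[drug]]
      }
      expected <- cfg$baseline_mean * 2^eff
      for (r in seq_len(nrep)) {
        sid <- sprintf("%s_r%d", drug, r)
        noise <- exp(stats::rnorm(length(genes), 0, cfg$noise_sd))
        cols[[sid]] <<- expected * noise
        meta[nrow(meta) + 1L, ] <<- list(sid, drug, cfg$dose_label,
                                         cfg$time_label, r, is_control)
      }
    }
    add_samples("DMSO", cfg$n_control_reps, TRUE)
    for (d in drugs) add_samples(d, cfg$n_reps, FALSE)
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    perturbagen_set(values, meta)
  })
}

#' Configuration for the gene-set generator
#'
#' @param n_terms number of terms in the collection.
#' @param term_size_range integer interval `c(lo, hi)` for random term sizes.
#' @param planted_term optional `list(name=, genes=)` included verbatim, e.g. a
#'   mock MHC-complex term overlapping a candidate's correlated genes.
#' @param seed integer seed.
#' @return A validated `gene_set_sim_config` list.
#' @export
gene_set_sim_config <- function(n_terms = 20L, term_size_range = c(10L, 40L),
                                planted_term = NULL, seed = 1L) {
  assert_count(n_terms, "n_terms")
  if (length(term_size_range) != 2L || term_size_range[1] > term_size_range[2] ||
      term_size_range[1] < 1L) {
    stop2("field 'term_size_range' must be an increasing positive integer pair")
  }
  assert_count(seed, "seed", min = 0L)
  if (!is.null(planted_term)) {
    if (!all(c("name", "genes") %in% names(planted_term))) {
      stop2("field 'planted_term' needs elements 'name' and 'genes'")
    }
    n <- length(unique(planted_term$genes))
    if (n < term_size_range[1] || n > term_size_range[2]) {
      stop2("planted_term size ", n, " outside term_size_range")
    }
  }
  structure(list(n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 planted_term = planted_term, seed = as.integer(seed)),
            class = "gene_set_sim_config")
}

#' Generate a gene-set collection over a gene universe
#'
#' Random terms are sampled without replacement within each term; the planted
#' term (if any) is included verbatim. Duplicate genes inside a term
#' specification are deduplicated with a warning.
#'
#' @param cfg a [gene_set_sim_config()].
#' @param universe character vector of gene names to draw from.
#' @return A [gene_set_collection()].
#' @export
make_gene_sets <- function(cfg, universe) {
  stopifnot(inherits(cfg, "gene_set_sim_config"))
  universe <- as.character(universe)
  if (!length(universe)) stop2("universe must be nonempty")
  with_seed(cfg$seed, {
    terms <- list()
    desc <- character()
    if (!is.null(cfg$planted_term)) {
      g <- as.character(cfg$planted_term$genes)
      if (anyDuplicated(g)) {
        warning("duplicate gene(s) in planted term '", cfg$planted_term$name,
                "' deduplicated", call. = FALSE)
        g <- unique(g)
      }
      outside <- setdiff(g, universe)
      if (length(outside)) {
        stop2("planted term contains genes outside the universe: ",
              paste(outside, collapse = ", "))
      }
      terms[[cfg$planted_term$name]] <- g
      desc[cfg$planted_term$name] <- "planted term"
    }
    n_random <- cfg$n_terms - length(terms)
    i <- 0L
    while (i < n_random) {
      i <- i + 1L
      size <- sample(seq(cfg$term_size_range[1],
                         min(cfg$term_size_range[2], length(universe))), 1L)
      nm <- sprintf("RANDOM_TERM_%03d", i)
      terms[[nm]] <- sample(universe, size)
      desc[nm] <- "random term"
    }
    gene_set_collection(terms, desc)
  })
}
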