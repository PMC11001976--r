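# Shared fixtures and independent oracles.

# Tiny labeled count matrix built by hand.
toy_expression <- function() {
  counts <- matrix(c(1, 0, 2, 3,
                     0, 4, 1, 0,
                     2, 2, 2, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("GA", "GB", "GC"),
                                   c("c1", "c2", "c3", "c4")))
  cells <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                      condition = c("malignant", "malignant", "normal", "normal"),
                      subtype = c("TNBC", "TNBC", "none", "none"),
                      patient = c("p1", "p1", "p2", "p2"),
                      stringsAsFactors = FALSE)
  labeled_expression_matrix(counts, cells)
}

# Perturbagen set from an explicit genes-x-samples value matrix; sample names
# of the form <drug>_r<i>, controls identified by drug id "DMSO".
toy_perturbagens <- function(values, dose = "10 uM", time = "24 h") {
  drug <- sub("_r[0-9]+$", "", colnames(values))
  rep_idx <- as.integer(sub("^.*_r", "", colnames(values)))
  meta <- data.frame(sample_id = colnames(values), drug_id = drug,
                     dose = dose, time = time, replicate = rep_idx,
                     is_control = drug == "DMSO", stringsAsFactors = FALSE)
  perturbagen_set(values, meta)
}

# Brute-force multiple-testing oracles, independent of stats::p.adjust.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- pmin(1, m * p[ord] / seq_len(m))
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

bonferroni_brute <- function(p) pmin(1, p * length(p))

# Exact upper-tail hypergeometric by summation over all achievable overlaps.
hyper_enum <- function(overlap, term_size, universe_size, module_size) {
  ks <- seq(overlap, min(term_size, module_size))
  if (!length(ks) || overlap < 0) return(1)
  sum(choose(term_size, ks) *
        choose(universe_size - term_size, module_size - ks)) /
    choose(universe_size, module_size)
}

# Split a vector of cell ids into two balanced groups within each patient.
split_within_patient <- function(cells, patients, seed) {
  set.seed(seed)
  groups <- unlist(lapply(split(cells, patients), function(cc) {
    stats::setNames(sample(rep(c("A", "B"), length.out = length(cc))), cc)
  }))
  names(groups) <- unlist(split(cells, patients))
  list(a = names(groups)[groups == "A"], b = names(groups)[groups == "B"])
}
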