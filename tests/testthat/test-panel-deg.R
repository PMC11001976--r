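# Normalization, variable-gene selection, hurdle test and plan derivation.

test_that("log-normalization matches hand arithmetic and its invariances", {
  counts <- matrix(c(1, 2,
                     1, 0,
                     2, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  norm <- log_normalize(counts, scale_factor = 1e4)
  expect_equal(norm["g1", "c1"], log(1 + 1e4 * 1 / 4))  # ln(1 + 2500)
  expect_equal(norm["g1", "c1"], 7.8244, tolerance = 1e-4)
  expect_equal(norm["g2", "c2"], 0)  # count 0 stays 0

  doubled <- counts
  doubled[, "c1"] <- doubled[, "c1"] * 2
  expect_equal(log_normalize(doubled)[, "c1"], log_normalize(counts)[, "c1"])

  bad <- counts
  bad[, "c2"] <- 0
  expect_error(log_normalize(bad), "c2")
})

test_that("normalization preserves within-cell ordering", {
  set.seed(1)
  counts <- matrix(rpois(200, 5), nrow = 20,
                   dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  norm <- log_normalize(counts)
  for (j in 1:10) {
    expect_identical(order(norm[, j]), order(counts[, j]))
  }
})

test_that("variable-gene selection excludes constants and finds overdispersion", {
  # a constant gene can never outrank a non-constant one
  counts <- matrix(rpois(500, 10), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("c%d", 1:10)))
  counts["g07", ] <- 4L
  top <- select_variable_genes(counts, n_top = 49)
  expect_false("g07" %in% top)

  # planted gene with ~10x the trend variance at its mean ranks first
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n_cells <- 200
    means <- exp(seq(log(0.5), log(20), length.out = 100))
    counts <- t(vapply(means, function(m) rpois(n_cells, m), numeric(n_cells)))
    rownames(counts) <- sprintf("g%03d", 1:100)
    # same mean as gene 50, far larger variance (NB with tiny size)
    counts[50, ] <- rnbinom(n_cells, mu = means[50], size = means[50] / 9)
    select_variable_genes(counts, n_top = 1) == "g050"
  }, logical(1))
  expect_gte(sum(hits), 4)

  expect_error(select_variable_genes(counts, n_top = 0), "positive")
  all_of_them <- select_variable_genes(counts, n_top = nrow(counts))
  expect_setequal(all_of_them, rownames(counts))
})

test_that("hurdle test reduces to its components in degenerate data", {
  set.seed(42)
  n <- 60
  cells_a <- sprintf("a%d", 1:n)
  cells_b <- sprintf("b%d", 1:n)
  # no zeros: pure continuous component, cross-checked against a direct
  # Gaussian likelihood-ratio computation
  y <- c(rnorm(n, 2, 0.3), rnorm(n, 2.4, 0.3))
  x <- matrix(y, nrow = 1, dimnames = list("g", c(cells_a, cells_b)))
  res <- hurdle_deg_test(x, cells_a, cells_b)
  g <- rep(c(1, 0), each = n)
  rss1 <- sum(resid(lm(y ~ g))^2)
  rss0 <- sum(resid(lm(y ~ 1))^2)
  p_oracle <- pchisq(2 * n * log(rss0 / rss1), df = 1, lower.tail = FALSE)
  expect_equal(res$pvalue, p_oracle, tolerance = 1e-12)

  # all positive values tied: pure detection component
  y2 <- c(rbinom(n, 1, 0.8), rbinom(n, 1, 0.3)) * 1.5
  x2 <- matrix(y2, nrow = 1, dimnames = list("g", c(cells_a, cells_b)))
  res2 <- hurdle_deg_test(x2, cells_a, cells_b)
  det <- as.numeric(y2 > 0)
  dev1 <- glm(det ~ g, family = binomial())$deviance
  dev0 <- glm(det ~ 1, family = binomial())$deviance
  expect_equal(res2$pvalue, pchisq(dev0 - dev1, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # undetected gene
  x3 <- rbind(x2, gz = 0)
  res3 <- hurdle_deg_test(x3, cells_a, cells_b)
  expect_equal(res3$flag[res3$gene == "gz"], "undetected")
  expect_equal(res3$pvalue[res3$gene == "gz"], 1)
  expect_equal(res3$lfc[res3$gene == "gz"], 0)
})

test_that("hurdle test detects a strong planted effect", {
  for (seed in 1:3) {
    cfg <- sc_sim_config(n_genes = 100, n_cells_per_group = 500,
                         panel_genes = "HIT", planted_lfc = c(HIT = 2.0),
                         seed = seed)
    m <- simulate_sc_counts(cfg)
    norm <- log_normalize(m)
    cd <- as.data.frame(SummarizedExperiment::colData(m))
    res <- suppressWarnings(hurdle_deg_test(
      norm, cd$cell_id[cd$condition == "malignant"],
      cd$cell_id[cd$condition == "normal"], genes = "HIT"))
    expect_lt(res$pvalue, 1e-6)
    expect_gt(res$lfc, 0)
  }
})

test_that("within-patient permutation gives uniform p-values", {
  cfg <- sc_sim_config(n_genes = 400, n_cells_per_group = 150,
                       n_patients_per_group = 4, seed = 20)
  m <- simulate_sc_counts(cfg)
  norm <- log_normalize(m)
  cd <- as.data.frame(SummarizedExperiment::colData(m))
  cells <- cd$cell_id[cd$condition == "normal"]
  grp <- split_within_patient(cells, cd$patient[match(cells, cd$cell_id)],
                              seed = 99)
  res <- hurdle_deg_test(norm, grp$a, grp$b)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the patient covariate is dropped with a warning when nested", {
  cfg <- sc_sim_config(n_genes = 20, n_cells_per_group = 40, seed = 2)
  m <- simulate_sc_counts(cfg)
  norm <- log_normalize(m)
  cd <- as.data.frame(SummarizedExperiment::colData(m))
  expect_warning(
    hurdle_deg_test(norm, cd$cell_id[cd$condition == "malignant"],
                    cd$cell_id[cd$condition == "normal"],
                    genes = rownames(norm)[1:3]),
    "dropping the patient covariate")
})

test_that("deregulation calls respect thresholds, boundaries and monotonicity", {
  rec <- data.frame(gene = c("a", "b", "c"), contrast = "t",
                    lfc = c(2, -2, 0.1), pvalue = c(1e-7, 0.19, 1e-7))
  out <- classify_deregulation(rec, alpha = 0.05, lfc_min = 0.25,
                               mt_method = "bonferroni")
  expect_identical(out$direction, c("up", "ns", "ns"))
  expect_true(all(out$padj >= out$pvalue))

  # padj exactly at alpha is ns (strict inequality)
  rec2 <- data.frame(gene = "a", contrast = "t", lfc = 2, pvalue = 0.05)
  out2 <- classify_deregulation(rec2, alpha = 0.05, mt_method = "bonferroni")
  expect_identical(out2$direction, "ns")

  # decreasing the p-value can never flip a significant call back to ns
  p_grid <- c(0.2, 0.04, 0.01, 1e-4, 1e-8)
  dirs <- vapply(p_grid, function(p) {
    classify_deregulation(data.frame(gene = "g", contrast = "t", lfc = 1,
                                     pvalue = p))$direction
  }, character(1))
  first_up <- match("up", dirs)
  if (!is.na(first_up)) expect_true(all(dirs[first_up:length(dirs)] == "up"))

  expect_error(classify_deregulation(rec[0, ]), "empty")
})

test_that("the repositioning plan reproduces the printed deregulation pattern", {
  panel <- read_panel_annotation(system.file("extdata", "panel_annotation.tsv",
                                             package = "ampReposition"))
  calls <- read.delim(system.file("extdata", "table1_deg_calls.tsv",
                                  package = "ampReposition"))
  plan <- build_reposition_plan(panel, calls)
  expect_setequal(plan$gene[plan$plane == "Down"], c("B2M", "SLPI"))
  expect_setequal(plan$gene[plan$plane == "Up"],
                  c("PIGR", "DEFB1", "LTF", "CLU", "S100A7", "SCGB2A1"))
  # no gene on both planes, and the plan never leaves the annotated panel
  expect_false(any(duplicated(plan$gene)))
  expect_true(all(plan$gene %in% panel$gene[panel$dr_direction != "None"]))
  # provenance names supporting contrasts
  expect_match(plan$provenance[plan$gene == "B2M"], "TNBC")
})

test_that("genes annotated None never enter the plan, whatever the calls", {
  panel <- data.frame(gene = c("BST2", "B2M"),
                      therapeutic_role = "x",
                      dr_direction = c("None", "Down"))
  calls <- data.frame(gene = rep(c("BST2", "B2M"), each = 1),
                      contrast = "TNBC_vs_normal",
                      direction = c("up", "up"))
  plan <- build_reposition_plan(panel, calls)
  expect_false("BST2" %in% plan$gene)

  # a Down-plane gene never observed up -> plan can become empty
  calls2 <- data.frame(gene = c("BST2", "B2M"), contrast = "TNBC_vs_normal",
                       direction = c("up", "down"))
  expect_error(build_reposition_plan(panel, calls2), "no actionable targets")
})

test_that("normalization and VST ranking agree with an independent implementation", {
  set.seed(31)
  counts <- matrix(rnbinom(300 * 60, mu = 3, size = 2), nrow = 300,
                   dimnames = list(sprintf("g%03d", 1:300), sprintf("c%02d", 1:60)))
  counts <- counts[, colSums(counts) > 0]
  norm_pkg <- log_normalize(counts)
  so <- suppressWarnings(Seurat::CreateSeuratObject(counts))
  so <- Seurat::NormalizeData(so, verbose = FALSE)
  norm_ref <- as.matrix(Seurat::GetAssayData(so, layer = "data"))
  expect_equal(max(abs(norm_pkg - norm_ref)), 0)

  so <- suppressWarnings(Seurat::FindVariableFeatures(
    so, selection.method = "vst", nfeatures = 50, verbose = FALSE))
  expect_setequal(select_variable_genes(counts, 50),
                  Seurat::VariableFeatures(so))
})
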