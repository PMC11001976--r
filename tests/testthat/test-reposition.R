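# Perturbagen filtering, LFC arithmetic, ranking, conflict and guard logic.

test_that("dose/time filtering keeps matching samples and reports drops", {
  vals <- matrix(10, nrow = 2, ncol = 8,
                 dimnames = list(c("g1", "g2"),
                                 c("DMSO_r1", "DMSO_r2", "DA_r1", "DA_r2",
                                   "DB_r1", "DB_r2", "DC_r1", "DC_r2")))
  meta <- data.frame(
    sample_id = colnames(vals),
    drug_id = sub("_r[0-9]$", "", colnames(vals)),
    dose = c("10 uM", "10 uM", "10 uM", "10 uM", "1 uM", "10 uM", "1 uM", "1 uM"),
    time = "24 h",
    replicate = rep(1:2, 4),
    is_control = grepl("DMSO", colnames(vals)))
  p <- perturbagen_set(vals, meta)
  pf <- filter_perturbagens(p, "10 uM", "24 h")
  kept <- colnames(pf)
  expect_setequal(kept, c("DMSO_r1", "DMSO_r2", "DA_r1", "DA_r2", "DB_r2"))
  expect_identical(attr(pf, "dropped_drugs"), "DC")

  # identity subset when everything matches
  p_all <- toy_perturbagens(vals)
  expect_equal(ncol(filter_perturbagens(p_all, "10 uM", "24 h")), ncol(p_all))
  expect_error(filter_perturbagens(p, "99 uM", "24 h"), "no treatment")
})

test_that("drug LFC matches hand arithmetic to machine precision", {
  vals <- cbind(DMSO_r1 = c(4, 2), DMSO_r2 = c(4, 6),
                DX_r1 = c(8, 1), DX_r2 = c(8, 3),
                DY_r1 = c(4, 2), DY_r2 = c(4, 6))
  rownames(vals) <- c("gA", "gB")
  lfc <- compute_drug_lfc(toy_perturbagens(vals), pseudocount = 0)
  expect_identical(lfc["gA", "DX"], 1)                     # (4,4) -> (8,8)
  expect_identical(lfc["gB", "DX"], -1)                    # (2,6) -> (1,3)
  expect_identical(unname(lfc[, "DY"]), c(0, 0))           # identical to control
  # log2-of-mean, not mean-of-log2: mean-of-log2 for gB/DX would give
  # mean(log2(1), log2(3)) - mean(log2(2), log2(6)) = -1 too, so check
  # a case where they differ
  vals2 <- cbind(DMSO_r1 = 2, DMSO_r2 = 8, DZ_r1 = 5, DZ_r2 = 5)
  rownames(vals2) <- "g"
  lfc2 <- compute_drug_lfc(toy_perturbagens(vals2))
  expect_equal(lfc2["g", "DZ"], 0)            # log2(5) - log2(5)
  expect_false(isTRUE(all.equal(
    lfc2["g", "DZ"], mean(log2(c(5, 5))) - mean(log2(c(2, 8))))))

  vals3 <- cbind(DMSO_r1 = 0, DMSO_r2 = 0, DW_r1 = 1, DW_r2 = 1)
  rownames(vals3) <- "g"
  expect_error(compute_drug_lfc(toy_perturbagens(vals3)), "pseudocount")
})

test_that("directional ranking sorts, truncates and breaks ties by drug id", {
  lfc <- matrix(c(-2, 0, 1), nrow = 1,
                dimnames = list("T", c("A", "B", "C")))
  down <- rank_drugs_for_gene(lfc, "T", "Down", k = 2)
  expect_identical(down$drug_id, c("A", "B"))
  up <- rank_drugs_for_gene(lfc, "T", "Up", k = 1)
  expect_identical(up$drug_id, "C")

  tied <- matrix(c(1, 1, 0), nrow = 1, dimnames = list("T", c("Z", "A", "M")))
  expect_identical(rank_drugs_for_gene(tied, "T", "Up", k = 3)$drug_id,
                   c("A", "Z", "M"))

  # permutation property: every drug exactly once before truncation
  set.seed(7)
  big <- matrix(rnorm(30), nrow = 1, dimnames = list("T", sprintf("D%02d", 1:30)))
  full <- rank_drugs_for_gene(big, "T", "Down", k = 30)
  expect_setequal(full$drug_id, colnames(big))
  expect_identical(full$rank, 1:30)

  expect_error(rank_drugs_for_gene(lfc, "Tx", "Up"), "not in LFC matrix")
})

test_that("panel conflict scores anti-plan movement only", {
  plan <- data.frame(gene = c("T1", "T2"), plane = c("Down", "Up"))
  lfc <- matrix(c(-2, -1.5,
                   -2, 0.1), nrow = 2,
                dimnames = list(c("T1", "T2"), c("X", "Y")))
  # evaluating X for T1: only T2 counts; lfc(T2, X) = -1.5 against Up plane
  expect_equal(as.numeric(panel_conflict_score("X", plan, lfc, exclude = "T1")),
               1.5)
  expect_equal(as.numeric(panel_conflict_score("Y", plan, lfc, exclude = "T1")),
               0)
  # fully aligned drug scores zero
  aligned <- matrix(c(-1, 2), nrow = 2, dimnames = list(c("T1", "T2"), "Z"))
  expect_equal(as.numeric(panel_conflict_score("Z", plan, aligned,
                                               exclude = NULL)), 0)
  # order of plan genes is irrelevant
  expect_equal(as.numeric(panel_conflict_score("X", plan[2:1, ], lfc, "T1")),
               as.numeric(panel_conflict_score("X", plan, lfc, "T1")))
})

test_that("contradictory-impact filtering excludes, re-ranks and is monotone in tau", {
  plan <- data.frame(gene = c("T1", "T2"), plane = c("Down", "Up"))
  lfc <- matrix(c(-2, -1.5,
                  -2, 0.1,
                  -0.5, 0.3), nrow = 2,
                dimnames = list(c("T1", "T2"), c("X", "Y", "W")))
  ranked <- rank_drugs_for_gene(lfc, "T1", "Down", k = 3)
  out0 <- filter_contradictory(ranked, plan, lfc, tau = 0)
  x_row <- out0[out0$drug_id == "X", ]
  expect_true(x_row$excluded)
  expect_match(x_row$exclusion_reason, "T2")
  expect_false(out0$excluded[out0$drug_id == "Y"])
  # survivors re-ranked from 1
  expect_identical(out0$rank[!out0$excluded], seq_len(sum(!out0$excluded)))

  out_inf <- filter_contradictory(ranked, plan, lfc, tau = Inf)
  expect_identical(out_inf$drug_id, ranked$drug_id)
  expect_false(any(out_inf$excluded))

  kept0 <- out0$drug_id[!out0$excluded]
  for (tau in c(0.5, 1, 2)) {
    kept_tau <- with(filter_contradictory(ranked, plan, lfc, tau = tau),
                     drug_id[!excluded])
    expect_true(all(kept0 %in% kept_tau))
    kept0 <- kept_tau
  }

  # a plan whose every drug conflicts warns per target
  lfc_bad <- matrix(c(-2, -3, -1, -2), nrow = 2,
                    dimnames = list(c("T1", "T2"), c("X", "Y")))
  rk <- rank_drugs_for_gene(lfc_bad, "T1", "Down", k = 2)
  expect_warning(filter_contradictory(rk, plan, lfc_bad, tau = 0),
                 "no candidate survives")
})

test_that("guard conflicts are summed over suppressed guard genes only", {
  lfc <- matrix(c(-0.4, 0.9,
                   0.2, 0.1,
                  -1.0, -0.5), nrow = 2,
                dimnames = list(c("H1", "H2"), c("DA", "DB", "DC")))
  lfc <- rbind(lfc, T1 = c(-2, -1.8, -1.9))
  cand <- data.frame(drug_id = c("DA", "DB", "DC"), target_gene = "T1",
                     plane = "Down", target_lfc = lfc["T1", ], rank = 1:3,
                     panel_conflict = 0, excluded = FALSE,
                     exclusion_reason = "")
  guards <- list(T1 = list(guard_genes = c("H1", "H2"), source_terms = "MHC"))
  rep <- guard_conflict_report(cand, guards, lfc)
  gc <- setNames(rep$candidates$guard_conflict, rep$candidates$drug_id)
  expect_equal(unname(gc["DA"]), 0.4)   # max(0, 0.4) + max(0, -0.9)
  expect_equal(unname(gc["DB"]), 0)     # no harm
  expect_equal(unname(gc["DC"]), 1.5)
  expect_identical(rep$candidates$drug_id[rep$candidates$recommended], "DB")
  # detail table covers every (drug, guard gene) pair
  expect_equal(nrow(rep$detail), 6)

  # empty guard set: zero conflict everywhere
  rep2 <- guard_conflict_report(cand,
                                list(T1 = list(guard_genes = character(),
                                               source_terms = character())),
                                lfc)
  expect_true(all(rep2$candidates$guard_conflict == 0))
})

test_that("recommendation ties break by larger target effect, then drug id", {
  lfc <- matrix(c(0.1, 0.1, 0.1,
                  -2, -1, -2), nrow = 2, byrow = TRUE,
                dimnames = list(c("H1", "T1"), c("DB", "DA", "DC")))
  cand <- data.frame(drug_id = c("DA", "DB", "DC"), target_gene = "T1",
                     plane = "Down", target_lfc = lfc["T1", c("DA", "DB", "DC")],
                     rank = 1:3, panel_conflict = 0, excluded = FALSE,
                     exclusion_reason = "")
  guards <- list(T1 = list(guard_genes = "H1", source_terms = "MHC"))
  rep <- guard_conflict_report(cand, guards, lfc)
  # all guard conflicts zero; DB and DC tie at |lfc| = 2 -> DB by drug id
  expect_identical(rep$candidates$drug_id[rep$candidates$recommended], "DB")
})
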