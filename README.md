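# ampReposition

Drug repositioning against immunomodulatory peptide genes in breast-cancer
epithelium, from single-cell expression and perturbagen profiles.

## The problem

Antimicrobial and immunomodulatory peptide (AMP) genes are deregulated in
malignant versus normal breast epithelial cells. Some (B2M, SLPI) are
overexpressed and favor progression and metastasis — a therapy should
**downregulate** them; others (PIGR, DEFB1, LTF, CLU, S100A7, SCGB2A1)
support immune elimination and are lost — a therapy should **upregulate**
them. But B2M sits inside the MHC antigen-presentation complex: any drug
that suppresses B2M and drags the correlated HLA genes down with it would
undermine the immune response it is meant to strengthen.

`ampReposition` implements this reasoning as a tested pipeline for
computational biologists:

1. **Panel DEG** — log-normalization
   (`ln(1 + 10^4 x/N)`), VST variable-gene selection, and a two-part
   *hurdle* differential-expression test per subtype-vs-normal contrast
   (logistic detection component + Gaussian continuous component on the
   positives, patient covariate in both, chi-square statistics and degrees
   of freedom summed), followed by `up`/`down`/`ns` calls
   (`padj < α`, `|lfc| ≥ lfc_min`) and derivation of the repositioning plan.
2. **Correlation & guards** — per-candidate Pearson modules over the
   variable genes (`r > 0.3`, Bonferroni `padj < 0.05`, top 50),
   hypergeometric gene-set enrichment (BH, top 5 terms), and guard sets
   from enriched terms matching name patterns (default `"MHC"`).
3. **Reposition** — perturbagen samples filtered to one dose/time
   ("10 uM"/"24 h"), drug scores
   `lfc(g,d) = log2(mean treatment) − log2(mean DMSO)` with replicate means
   on the linear scale, directional per-target ranking, exclusion of drugs
   whose anti-plan movement across the rest of the panel exceeds `tau`, and
   a guard-conflict report `Σ_h max(0, −lfc(h,d))` that flags the
   minimal-conflict surviving drug per guarded target as `recommended`.
4. **Synthetic data** — negative-binomial single-cell counts with planted
   condition effects, patient batch shifts, dropout and a planted
   co-expression module; a DMSO-controlled perturbagen panel with planted
   per-drug effect vectors; GMT gene-set collections with a planted term.
   Every downstream stage is testable without any download.

See `vignettes/amp-repositioning-methods.Rmd` for the model details and the
design decisions.

## Worked example

```r
library(ampReposition)
cfg <- pipeline_config(out_dir = "amp_out", seed = 1)
res <- run_all(cfg, quiet = TRUE)

res$candidates[res$candidates$recommended,
               c("drug_id", "target_gene", "plane", "target_lfc", "guard_conflict")]
#>     drug_id target_gene plane target_lfc guard_conflict
#>   CLEAN_B2M         B2M  Down     -0.882              0
#>      UP_CLU         CLU    Up      1.188              0
#>    UP_DEFB1       DEFB1    Up      1.048              0
#>      UP_LTF         LTF    Up      1.173              0
#>     UP_PIGR        PIGR    Up      1.230              0
#>   UP_S100A7      S100A7    Up      1.071              0
#>  UP_SCGB2A1     SCGB2A1    Up      1.114              0
#>  CLEAN_SLPI        SLPI  Down     -1.348              0
```

The plan (written to `amp_out/plan.tsv`) contains the eight actionable
targets — B2M and SLPI on the Down plane, the six protective genes on the
Up plane — each with the subtype contrasts that support it. For every
target the table lists ranked drugs with their target LFC (here the planted
upregulators at ≈ +1.2 log2 and the planted suppressors at ≈ −1.2, both
within replicate noise of their planted effects), the panel-conflict score
that excluded contradictory drugs, and the guard conflict.

The guarded B2M case shows the selection pattern the pipeline exists for:

```r
res$candidates[res$candidates$target_gene == "B2M" &
               res$candidates$drug_id %in% c("CLEAN_B2M", "DIRTY_B2M"),
               c("drug_id", "target_lfc", "panel_conflict", "guard_conflict", "recommended")]
#>    drug_id target_lfc panel_conflict guard_conflict recommended
#>  DIRTY_B2M     -1.297          0.398           3.05       FALSE
#>  CLEAN_B2M     -0.882          0.231           0.00        TRUE
```

Both drugs suppress B2M, but the dirty one also pulls the seven derived
guard genes (HLA-A/B/C, HLA-DMA, HLA-DRA, HLA-DRB1, TAP1) down by ~1 log2
each, accumulating a guard conflict of 3.05; the clean, MHC-sparing drug is
the one flagged `recommended`.

A command-line wrapper is installed as `exec/amp-reposition`:

```sh
amp-reposition run-all --config inst/extdata/default_config.yaml --out-dir amp_out
```

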