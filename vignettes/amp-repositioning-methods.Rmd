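---
title: "Methods: repositioning drugs against immunomodulatory peptide genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repositioning drugs against immunomodulatory peptide genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Antimicrobial and immunomodulatory peptide (AMP) genes are deregulated in
breast-cancer epithelium relative to normal breast epithelium. Some of them
(e.g. B2M, SLPI) are overexpressed and favor tumor progression; others (PIGR,
DEFB1, LTF, CLU, S100A7, SCGB2A1) support immune elimination of tumor cells
and are lost or unchanged. This package implements a desk-scale pipeline
that (i) tests an AMP panel for differential expression between malignant
and normal epithelial cells in single-cell data, (ii) derives each
candidate's correlated-gene neighbourhood and, from enriched gene sets,
*guard genes* (such as the MHC/HLA antigen-presentation machinery around
B2M) that a therapeutic perturbation must not co-suppress, and (iii) ranks
drug perturbagens from a DMSO-controlled expression panel by a
replicate-aggregated log2 fold-change score, filtering drugs whose effects
on the rest of the panel contradict the plan.

Everything runs on synthetic data with planted structure; the generators are
first-class, tested components, and all statistical claims below are backed
by the test suite.

## Differential expression: the two-part hurdle test

Log-normalization is the standard per-cell transform
$y_{gc} = \ln(1 + s\,x_{gc}/N_c)$ with scale factor $s = 10^4$ (the
convention of single-cell toolkits) and library size $N_c$.

Single-cell expression is zero-inflated: a gene is either undetected in a
cell or detected at a positive level. The hurdle test therefore combines

1. a **detection component**: a logistic regression of $\mathbb{1}[y > 0]$
   on the contrast group, with the patient label as a fixed-effect
   covariate, assessed by a likelihood-ratio chi-square; and
2. a **continuous component**: a Gaussian likelihood-ratio test of the group
   effect on the positive values, with the same covariate.

The two chi-square statistics and their degrees of freedom are summed and
referred to a chi-square distribution — the classical combination for
independent hurdle components. The test degenerates gracefully: with no
zeros it is exactly the continuous component, and with all positive values
tied it is exactly the detection component.

The reported effect size is
$\mathrm{lfc} = \log_2\frac{\overline{\mathrm{expm1}(y_A)} + \varepsilon}
{\overline{\mathrm{expm1}(y_B)} + \varepsilon}$ with pseudocount
$\varepsilon = 1/\min(n_A, n_B)$, which keeps group-exclusive genes finite.

**Patient covariate and nesting.** In a real malignant-vs-normal contrast
every patient belongs to one group, so patient fixed effects are collinear
with the group effect; in that case the covariate is dropped with a warning
and the test is a plain two-group hurdle test. The covariate earns its keep
whenever groups are formed within patients — the package demonstrates
calibration on within-patient null splits of batched data, where the
empirical type-I rate at $p < 0.05$ sits inside $[0.03, 0.07]$ and the
p-value distribution is uniform under within-patient permutation (see the
test suite). Mixed-effects and pseudobulk alternatives are deliberately out
of scope.

**Direction calls.** Per contrast, p-values are adjusted
(Benjamini–Hochberg by default; Bonferroni available) and a gene is called
`up` / `down` only when `padj < alpha` (strict inequality, default
`alpha = 0.05`) *and* $|\mathrm{lfc}| \ge$ `lfc_min` (default 0.25, the
usual single-cell reporting convention). These two defaults are declared
package conventions, not estimates of anything.

**Plan derivation.** The panel annotation assigns each gene a repositioning
plane: `Down` for tumor-promoting AMPs, `Up` for protective ones, `None`
for genes that are markers only or behave inconsistently across
malignancies. A `Down` gene enters the plan when it is observed `up` in at
least one subtype contrast (there is something to suppress); an `Up` gene
enters when it is `down` or `ns` in at least one contrast (there is
something to restore). Any non-`up` call is treated as compatible with the
`Up` plane — the annotation table distinguishes "downregulated" from "not
available/ns" loosely, so the permissive reading is the safe one.

## Variable genes and correlation modules

Variable genes are ranked by the variance-stabilizing-transform criterion:
a loess trend of $\log_{10}$ variance on $\log_{10}$ mean of the raw
counts, per-gene standardization by the trend-predicted SD with clipping at
$\sqrt{n_\mathrm{cells}}$, then ranking by the variance of the clipped
standardized values. The default of 3000 genes follows common single-cell
practice; the bundled synthetic study uses 300 of its 600 genes, scaled to
its universe.

For each plan candidate, Pearson correlation is computed against every
other variable gene across cells, with the analytic two-sided p-value from
the $t$ transform on $n - 2$ degrees of freedom (a permutation null backs
this up in the tests). Genes with $r >$ `r_min` (default 0.3, *signed* —
the module is meant to capture co-regulated partners, and the guard logic
only makes sense for positive co-expression) and Bonferroni-adjusted
$p <$ 0.05 are retained, capped at the top 50 by $r$ (ties broken by gene
name for determinism). The Bonferroni multiplier is the number of partner
tests per candidate; a global correction across candidates would conflate
module sizes with panel size.

Enrichment of a module against a GMT collection is the one-sided upper-tail
hypergeometric test on the universe of *measured* genes (terms are
intersected with the universe first, preventing inflation from
unmeasurable genes), with BH adjustment across terms and the top five
significant terms reported. Guard sets are then mechanized from what a
reader does by eye: enriched terms whose names match configured patterns
(default `"MHC"`) contribute their member genes, minus the candidate
itself, intersected with the measured universe.

## Perturbagen scoring

Perturbagen profiles are linear-scale expression values with sample
metadata (drug, dose, time, replicate, control flag). Samples are filtered
to one dose/time condition (default "10 uM" / "24 h") for both treatments
and DMSO controls. The drug score is

$$\mathrm{lfc}(g, d) = \log_2\big(\overline{x}_{g,d} + c\big) -
  \log_2\big(\overline{x}_{g,\mathrm{DMSO}} + c\big),$$

replicate means taken **on the linear scale first** (log2-of-mean, not
mean-of-log2 — the two differ whenever replicates disagree, and the package
treats the order as part of the method's definition). The pseudocount $c$
defaults to 0 and must be set positive by callers whose data can produce
zero replicate means; the caller is responsible for declaring that the
input is linear-scale.

Per target, drugs are sorted by the target's LFC along the plane
(descending for `Up`, ascending for `Down`; ties by drug id) and the top
$k$ kept. Both $k = 50$ (the reporting default) and $k = 20$ are sensible;
the reporting cap is exposed as configuration.

**Contradiction filter.** For a drug evaluated on target $t$, the panel
conflict is $\sum_{g \ne t} \max(0, s_g \cdot (-\mathrm{lfc}(g, d)))$ with
$s_g = +1$ for `Up`- and $-1$ for `Down`-plane genes — the total magnitude
of anti-plan movement. A magnitude score was chosen over a binary
sign count so that a tolerance `tau` has physical units (log2 fold change);
`tau = 0` reproduces strict sign-based exclusion. Because replicate noise
makes exact zeros measure-zero events, the bundled pipeline default is
`tau = 0.5`, roughly five times the per-gene LFC noise floor of the
synthetic panel (noise SD 0.1, three replicates), while the function-level
default stays 0. The filter is monotone in `tau` by construction.

**Guard conflict.** For each candidate row whose target carries a guard
set, the guard conflict is $\sum_{h} \max(0, -\mathrm{lfc}(h, d))$ over
guard genes $h$ — the total suppression inflicted on the guard set. Per
guarded target the surviving drug with minimal guard conflict is flagged
`recommended` (ties: larger absolute target LFC, then drug id). This is the
package's quantitative operationalization of "least conflict with the MHC
complex"; no single canonical definition exists, and the additive form
makes the two-drug clean/dirty fixture separable by construction.

## What the generators emulate — and what they do not

`simulate_sc_counts` draws negative-binomial counts with gene-level
log-normal means (sdlog 1) around `base_mean` (default 2, a shallow
10x-like depth for a 600–1000-gene universe), planted malignant-condition
log2 effects on panel genes, an additive per-patient shift on the log mean
(`batch_sd`, default 0.1), an optional latent-factor co-expression module,
and independent Bernoulli dropout (default 0.1) on top of the NB zeros.
Zero fractions land near 35%, so the hurdle test's detection component has
signal. The co-expression module multiplies the expected expression of an
anchor (B2M) and its partners (HLA genes) by $\exp(\text{strength} \cdot f_c)$
with a standard-normal per-cell factor $f_c$; with strength 2 and module
base mean 25 the realized pairwise correlations on the normalized log scale
are ~0.3–0.5 — comfortably above the module threshold, as the strong
MHC co-expression it mimics would be. Because library-size normalization
removes any factor shared by the whole library, the module must (and does)
occupy a modest fraction of the library; this is why module genes carry
their own abundance parameter.

Not emulated: UMI-level sampling, cell-type mixtures, doublets, mean-dependent
dropout, cross-platform batch (anchor-based dataset integration is out of
scope — the patient covariate carries the batch burden instead), and
any chromatin or proteomic layer. Passing tests therefore demonstrate the
statistical machinery under the stated generative assumptions, not
performance on real tissue atlases.

`simulate_perturbagen_panel` plants per-drug log2 effect vectors on a
baseline of 100 with multiplicative log-normal noise (SD 0.1) and a single
DMSO pseudo-drug with six control replicates; since
$E[\text{mean of replicates}]$ carries the same log-normal bias factor in
treatment and control, the planted effect is recovered unbiasedly by the
log2-of-mean score.

All randomness flows from one master seed; stage sub-seeds are
`(seed * 2099 + 9973 * offset) mod (2^31 - 1)`, so any stage can be
regenerated independently and `run_all` is bit-reproducible (hash-verified
in the manifest).

## Numerical and degenerate-input choices

* `padj` exactly equal to `alpha` is *not* significant (strict inequality).
* A gene undetected in both groups is flagged `undetected` with $p = 1$,
  lfc 0, rather than dropped — bookkeeping stays rectangular.
* Zero-variance candidates yield empty, flagged modules; constant partner
  genes are skipped and counted.
* Correlation p-values clip $|r|$ just below 1 so a perfect duplicate gets
  $p = 0$ without dividing by zero.
* Ties at the `top_n` correlation boundary and at ranking boundaries break
  lexicographically; recommendation ties break by effect size then id.
* All-zero cells are a hard error at normalization (they have no library
  size), listing the offending cells.

## Problem sizes

The bundled study simulates 600 genes x 800 cells (two conditions, three
patients each) and a 51-drug x 600-gene perturbagen panel; the calibration
checks in the tests use up to 1000 genes x 400 cells (type-I), 20 seeds of
1000-cell recovery runs, and 200-drug ranking panels. These sizes were
chosen so the statistical targets (type-I rate, recovery rates) are
estimated with useful precision while the whole suite stays interactive.

## Known limitations

* The hurdle test's continuous component assumes approximate normality of
  positive log-normalized values; it leans on sample sizes in the hundreds
  of cells, not on small clusters.
* With fully nested patients the test cannot separate patient from
  condition effects; results on such contrasts carry the usual
  pseudo-replication caveat of cell-level single-cell DEG.
* Guard derivation is name-pattern based; an ontology-aware roll-up of
  related terms is out of scope.
* The perturbagen module assumes linear-scale input and replicate
  exchangeability; moderated z-score collapsing of the kind used in
  level-5 LINCS processing is out of scope.
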