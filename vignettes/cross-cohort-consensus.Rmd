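---
title: "Cross-cohort consensus selection of expression markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort consensus selection of expression markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmarker)
```

## The problem

A gene that marks a disease reliably should mark it in more than one cohort,
on more than one array platform, and ideally in more than one kind of
sample. Single-cohort differential-expression lists are notoriously
unstable: platform panels differ, group sizes differ by an order of
magnitude, and a gene that tops one ranking may sit mid-table in the next.
`crossmarker` implements a consensus procedure for exactly this situation,
motivated by multi-cohort case-control studies of systemic lupus
erythematosus (SLE) in blood-born samples, where the canonical design is
four public cohorts — sorted monocytes (5 cases / 5 controls), PBMC
(61/20), and two whole-blood cohorts (99/30, 157/20) — on three different
microarray platforms.

The procedure has two independent routes to a selection, and the final
markers must survive both:

* **Marginal route.** Each gene is tested in each cohort on its own:
  linear-scale fold change $\mathrm{FC}_g = 2^{\bar x^{case}_g - \bar
  x^{ctrl}_g}$ (log2 data), a two-sample $t$-test, and
  Benjamini–Hochberg adjustment of the $t$-test $p$-values. Three selection
  rules are applied per cohort: the top $k = 100$ genes by FC, the top
  $k = 100$ by $t$-test $p$, and all genes with $q \le 0.001$. A gene earns
  a method's *consensus vote* if that method selected it in at least $m = 3$
  of the $n = 4$ cohorts; the union of the three methods' post-vote sets is
  the **marginal pool**.
* **Joint route.** All genes enter one $L_1$-penalised logistic regression
  of case/control status per cohort (`glmnet`), with the penalty chosen by
  stratified cross-validated binomial deviance; the selected genes are the
  nonzero coefficients. Per-cohort selections are aggregated into the
  **joint pool** (see *Aggregating the joint route* below).
* **Common markers** are the intersection of the marginal pool and the
  joint pool. The inclusion–exclusion identity
  $|A \cup B| = |A| + |B| - |A \cap B|$ is asserted on every run.

Before any of this, cohorts are harmonised: probe rows are collapsed to
official gene symbols using a per-platform annotation and all cohorts are
restricted to their commonly profiled genes, in fixed lexicographic order.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_k` | 100 genes | depth of the two ranking rules, per cohort |
| `fdr_alpha` | 0.001 | BH-adjusted significance level (selection uses $\le$) |
| `m_required` | 3 of $n$ cohorts | consensus vote threshold |
| `fc_rank_mode` | `"magnitude"` | rank $\max(\mathrm{FC}, 1/\mathrm{FC})$; `"ratio"` ranks up-regulation only |
| `t_variant` | `"welch"` | Welch unequal-variance $t$; `"student"` pools variances |
| `collapse_rule` | `"max_mean_probe"` | probe with highest overall mean represents the gene |
| `joint_mode` | `"pooled"` | union of per-cohort lasso selections; `"consensus"` applies the m-of-n vote |
| `lasso$n_folds` | 10 | stratified CV folds (leave-one-out below 10 per class) |
| `lasso$lambda_rule` | `"min_deviance"` | CV-minimising penalty; `"one_se"` for the sparser 1-SE rule |

`top_k` is a *depth*, not a significance level: with 100 of ~6,000–7,000
common genes it takes the top ~1.5%. When running on much smaller panels
(unit tests, toy studies), scale it with the panel or the m-of-n filter
loses its meaning — at `top_k = 100` of 300 genes, a third of the panel is
"selected" everywhere and consensus votes become cheap.

Welch's $t$ is the default because the group sizes are severely unbalanced
(157 vs 20) and equal variances across case/control cannot be assumed in
real data. At the 5/5 monocyte cohort Welch is slightly conservative
(its null rejection rate at $\alpha = 0.05$ is ≈ 0.046 under the
generator's equal-variance model, where the Student variant is exact); the
calibration tests therefore check exactness with the Student variant and
check Welch for conservatism only.

## Aggregating the joint route

How per-cohort lasso selections should combine into one joint pool is
genuinely open: a published joint list's aggregation rule is usually not
recoverable from the text. We implemented both options and chose the
default by parameter recovery on synthetic studies with known truth:

* `"consensus"` (m-of-n on lasso selections, symmetric with the marginal
  methods) recovers a median of only ~5–7 of 15 planted markers under the
  four-cohort design. The reason is structural, not a tuning artefact: a
  cross-validated lasso is a sparse *model* selector, not a per-gene test.
  In any one cohort a true marker is routinely shadowed by a correlated
  neighbour, and the 5/5 cohort cannot carry more than ~9 nonzero
  coefficients at all, so demanding simultaneous selection in 3 of 4
  cohorts discards most true markers.
* `"pooled"` (union over cohorts) recovers a median of 13 of 15 with a
  median of 0 false positives. Its permissiveness is harmless here because
  the joint pool is never reported alone: false positives are controlled by
  the final intersection with the marginal consensus pool, which a noise
  gene only enters by passing an m-of-n vote.

`"pooled"` is therefore the default; `"consensus"` remains available via
`analysis_config(joint_mode = "consensus")`.

## The synthetic study generator

`generate_multidataset()` exists so that every downstream stage is testable
against known truth without downloading anything. Its defaults *are* the
study conditions described above, via `default_study_config()`:

* control log2 expression of gene $g$: $\mathcal N(\mathrm{baseline}_g,\
  \sigma)$ with $\mathrm{baseline}_g \sim U(6, 12)$ and $\sigma = 0.5$ —
  the standard log-normal-intensity assumption, with a within-group SD
  typical of processed microarray data;
* cases add $a_{\text{type}} \cdot \delta_g$ to planted markers, with
  attenuation $a = 1.0 / 0.6 / 0.15$ for monocyte / PBMC / whole blood,
  emulating the dilution of a monocyte-expressed interferon signature
  across sample types (the canonical ten-gene SLE panel shows interferon
  gene FC ranges of 8.82–251.66 in monocyte vs 3.73–74.05 in PBMC vs
  1.19–1.87 in whole blood);
* each gene expands to 1–3 probes: probe value = gene value + per-probe
  constant offset $\mathcal N(0, 0.2)$ + iid noise $\mathcal N(0, 0.25)$,
  giving multi-probe genes distinct but correlated rows (this is what makes
  the probe-collapse step non-trivial), plus ~2% unannotated probes that
  collapse must drop;
* platform panels are the shared core plus platform-private genes (20% of
  the core size), so the cross-cohort gene intersection is *exactly* the
  core — the invariant the harmonise stage is tested against;
* the RNG is forked deterministically per platform and per cohort, so
  adding a cohort never perturbs earlier cohorts' data, and everything is
  reproducible from one integer seed.

What the generator deliberately does **not** emulate: gene–gene
correlation, batch effects, platform-specific intensity distributions,
disease-activity covariates, age/sex structure. Passing the calibration and
recovery tests therefore shows the *procedure* is sound (calibrated under
its stated model, able to recover planted truth), not that any particular
real-data marker list is correct. In particular, with independent genes the
lasso route is easier than in real data, where co-expression makes sparse
selection less stable — one more reason the joint route is aggregated
permissively and disciplined by the marginal intersection instead.

## Numerical and degenerate-input choices

* **Scale heuristic.** Marginal statistics require log2 data. A collapsed
  matrix with maximum value above 50 is treated as linear intensities and
  transformed by $\log_2(x + 1)$ (log2 microarray data rarely exceeds ~16;
  linear intensities run into the thousands); negative values alongside a
  maximum above 50 are ambiguous and raise an error rather than guess.
* **Probe-collapse ties** (two probes with equal mean) break by probe id,
  and output genes are in lexicographic order, so collapse is invariant to
  input row order.
* **Ranking ties** in `select_top_k` break by gene symbol, making the
  selection canonical; exactly `min(k, #genes)` genes are always returned.
* **Zero-variance genes**: $t = 0,\ p = 1$ when group means agree (and both
  variances vanish), $p = 0$ when they differ — conventions that keep the
  vectorised statistics total instead of propagating `NaN`.
* **FDR selection** uses $q \le \alpha$, reading "FDR = 0.001" as a level.
* **Lasso determinism**: stratified folds are dealt from a fixed seed;
  cohorts whose smaller class has fewer members than `n_folds` fall back to
  leave-one-out folds (10-fold is impossible at $n = 10$). The penalty grid
  descends from $\lambda_{\max}$, the smallest penalty with the all-zero
  solution; at $\lambda_{\max}$ the selection is empty by construction.
  Solutions are validated in the test suite against the KKT subgradient
  conditions of the penalised objective and against a generic
  bound-constrained convex solver (L-BFGS-B on the split-variable form).
* **Enrichment** is a plain hypergeometric upper tail against a
  user-supplied GMT, with terms intersected with the stated universe and BH
  across terms. There is no ontology propagation and no web service; with
  an unstated universe, published GO $p$-values are not reproducible and
  are not treated as targets. The natural universe is the commonly profiled
  gene set from the harmonise step.
* **PPI "isolation"** is degree 0 in the subgraph induced by the two gene
  sets; longer indirect paths through outside nodes are out of scope.

## Problem sizes used in validation

The shipped validation batteries run the full pipeline at the real study's
sample sizes with a 2,000-gene shared core — large enough that top-100
selection takes the top 5% and small enough that a 20-replicate battery is
a routine desk-scale computation. Under these conditions the test suite
asserts: pooled null type-I error inside the 99% binomial band (Student
variant), no common markers in ≥ 18 of 20 null replicates, and recovery of
a median ≥ 13 of 15 planted markers with a median ≤ 2 false positives.
`scripts/acceptance.R` recomputes all of these from scratch, plus the
oracle-equivalence checks for the BH and hypergeometric primitives.

## Known limitations

* The consensus is voting-based; it does not pool effect sizes. A gene just
  under the top-100 line in two cohorts earns no credit for near-misses —
  meta-analytic pooling (fixed/random effects) is deliberately out of
  scope.
* `max_mean_probe` keeps one probe per gene; for genes whose probes
  disagree (splice variants, cross-hybridisation) the choice is a
  convention, not a correction. `mean_of_probes` is available for
  sensitivity analysis.
* The FDR rule at $\alpha = 0.001$ is far stricter in a 10-sample cohort
  than in a 177-sample cohort; in practice it contributes votes mainly from
  the large cohorts. This mirrors how such thresholds behave on published
  per-cohort tables, where small-cohort FDR columns are mostly
  non-significant.
* With strongly correlated gene modules, per-cohort lasso selections
  fluctuate between module members; interpreting the joint pool gene by
  gene is unwise. The intersection with the marginal pool is the quantity
  the package stands behind.
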