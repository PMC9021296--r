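---
title: "Methods: quantifying treatment rescue of a disease transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying treatment rescue of a disease transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degrescue)
```

This vignette documents the models behind `degrescue`, the choices made
where the methodology was genuinely open, and what the synthetic-data
validation does and does not demonstrate about real data.

## The design and the question

The package targets a 2×2 layout: genotype (WT vs a disease model such as
3xTg) crossed with treatment (vehicle D vs drug S), with a handful of
bulk RNA-seq replicates per cell and optionally a multiplexed single-cell
experiment carrying cluster and subcluster labels. The question is not
merely "which genes change in disease" but "which disease changes does
the treatment revert" — a set-level property of two differential
expression contrasts sharing the same control group.

## Bulk differential expression

### Normalization

Size factors are median-of-ratios: for each sample, the median over
zero-free genes of the ratio between the sample's count and the gene's
geometric mean across samples, rescaled to geometric mean 1. When no gene
is zero-free the default is to stop with an error rather than silently
change estimand; `zero_policy = "pseudo"` switches to a 0.5-pseudocount
reference.

Because strongly asymmetric differential expression biases the median,
`deges_normalize()` iterates: compute factors, call putative DEGs between
the two contrast groups at p ≤ 0.01, recompute factors on the remaining
genes, three times by default. On data without DE structure the
elimination step is a fixed point after the first round, so the iteration
count is cheap insurance rather than a sensitive parameter.

### The test

For gene $g$ with counts $y_{gi}$ and size factors $s_i$, the model is
$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and $\mu_{gi} = s_i q_{g}$ under the
null or $s_i q_{g,\mathrm{group}(i)}$ under the alternative. Means are
fitted by Newton iteration on $\log q$ (tolerance $10^{-8}$, at most 100
steps, damped); the statistic $2(\ell_1 - \ell_0)$ is referred to
$\chi^2(1)$. All-zero genes are reported with $p = 1$ and zero fold
change; the fold change elsewhere is
$\log_2\!\big((q_B + c)/(q_A + c)\big)$ with pseudocount $c = 0.125$ so
single-group zeros stay finite.

### Dispersion

$\alpha_g$ is a pooled within-group moment estimate on normalized counts,
with the Poisson term scaled by $\overline{1/s}$, floored at $10^{-8}$,
and **shared between the null and alternative fits** so the test has one
degree of freedom.

A raw gene-wise estimate from 6–10 residual degrees of freedom is noisy
enough that the $\chi^2$ null is visibly anti-conservative: in null
simulations at $n = 4$ per group the fraction of genes at $p < 0.01$ is
roughly 0.04–0.05 with unmoderated estimates, whether moment-based or a
Cox–Reid adjusted profile MLE. This is the well-known reason the field's
DE tools moderate dispersions across genes. `degrescue` therefore shrinks
each gene-wise value toward a mean–dispersion trend (genes binned by
average expression rank, at most 20 bins; bin means form the trend) with
weight `prior_df = 10` against the residual degrees of freedom. With
moderation the same null simulations sit at 0.014–0.016 — calibrated
slightly above nominal, as expected with estimated dispersions.
`moderation = "none"` restores the raw gene-wise behaviour for users who
want it.

The DEG threshold is **inclusive** (p ≤ α): the reported gene lists are
what the threshold describes, and the comparator is exposed
(`comparator = "lt"`) for the strict reading. Raw p-values are used for
bulk DEG calling by default — the rescue logic is defined on thresholded
lists, and an FDR column can always be added downstream with
`p.adjust()`.

One property deliberately *not* claimed: exact invariance of p-values
under rescaling of one sample's counts. Tripling a sample's counts
triples its information content at the same normalized mean, and any
genuine count likelihood must notice. The invariances that do hold —
fold changes and normalized means up to scale, p-value stability — are
what the test suite asserts.

## Rescue classification and magnitude

`classify_rescue()` is pure set arithmetic on the two DEG lists and
inherits its correctness from the partition identities
(Restored + Maintained = |A|, Maintained + New = |B|), which are
property-tested on random lists. Direction is ignored by default: a gene
significant in both contrasts is Maintained even if its direction flips,
matching a Venn on unsigned lists; `signed = TRUE` instead splits such a
gene into Restored-and-New.

Restoration magnitude is computed on $\log_2(\text{normalized mean} + 1)$
— the expression space is a choice, not a given; the pseudocount avoids
$\log 0$ and the log scale makes "percent of the gap closed" symmetric
for up- and down-regulated genes. Genes whose disease–control gap is
below $10^{-6}$ on the log scale are excluded (the ratio is unstable) and
counted. Values can exceed the 0–100 range downward: overshoot beyond the
original gap is negative restoration, and the summary is the plain
arithmetic mean.

Reported percentages throughout the package round half away from zero.

## Keyword categories and over-representation

Category curation matches lowercase keyword stems against gene-**set**
names, never against gene symbols: "immun" matches `AUTOIMMUNE_DISEASE`
as a substring because the stems are stems. All supplied sets are
eligible by default — if a prior enrichment filter is wanted, filter the
collection before curating. Over-representation uses the upper-tail
hypergeometric probability; it is a deliberately lightweight stand-in for
full GO tooling, with optional Benjamini–Hochberg across sets.

## IEG panel

The 18-gene immediate-early-gene panel is a figure-level choice in the
source study, so the panel is a required input; `ieg_default_panel()`
ships only the four text-named members (Egr1, Fos, Arc, Bdnf) as a
convenience. Z-scores standardize each gene across **all** samples
(heatmap convention, n−1 denominator; constant genes get a zero row).
"Down-regulated" defaults to significant-and-down at the bulk threshold,
with `mode = "mean"` for the loose reading. The per-sample panel score is
the mean z-score over panel genes; it is compared with a 2×2 factorial
`aov()` and single-step Dunnett contrasts against WT-D via `multcomp`,
whose multivariate-t integration uses a quasi-Monte-Carlo rule — the RNG
is fixed locally so results are reproducible to the digit.

## Single-cell landscape

QC thresholds read "min 1000 UMIs" and "max 27% mitochondrial" as
inclusive keep-rules. Cluster and subcluster labels are inputs: embedding
and graph clustering live upstream of this package on purpose, because
the analyses of interest — composition, activation, markers — start from
labels.

The activation score of a lineage is its transitional-plus-active cell
count as a percentage of the resting (RH1 + RH2) count. It is a ratio of
counts within group, hence identical whether computed from raw counts or
a percentage table, and 100 means parity.

Marker detection normalizes each cell to a common total (10,000) and
takes $\ln(1 + x)$, then applies a two-sided Wilcoxon rank-sum test per
gene with mid-ranks. For groups of at most 8 cells the p-value is the
exact tail probability over all label assignments (correct under the
heavy ties of count data, which is why `wilcox.test`'s exact mode is not
usable here); larger groups use the tie-corrected normal approximation
with continuity correction, which null simulations show is calibrated at
the 5% level. Bonferroni is the default multiplicity correction for
markers — conservative, matching the convention of the single-cell
toolchain the analysis mirrors — with Benjamini–Hochberg behind a flag.
No minimum-expression or fold-change prefilter is applied by default;
such filters change the multiplicity burden and are left to the caller.

## Synthetic data: what it emulates and what it does not

`simulate_bulk_counts()` draws NB counts with a constant baseline mean
(default 100), a single dispersion (default 0.1), an effect size
(default |log2 FC| = 2 with random sign) and four gene classes — null,
restored (shifted in disease, reverted by treatment), maintained (shifted
in both), new (shifted only under treatment) — apportioned by
largest-remainder so class counts are exact. Per-sample size factors are
log-normal (σ = 0.2) so normalization is non-trivial. Class counts,
moments, and the Poisson limit at α → 0 are tested against theory.

`simulate_cell_table()` draws per-group subcluster identities
multinomially (control-group defaults follow a 43%-resting hippocampal
composition, the resting pool split 28/15; disease and treatment groups
are plausible invented shifts), log-normal UMI totals, Beta-distributed
mitochondrial fractions, and multinomial gene counts over a fixed
background profile with subcluster markers elevated 8-fold — so a cell's
UMI count equals its column sum by construction.

What the generators do **not** emulate: gene–gene correlation, per-gene
baseline heterogeneity, batch structure, ambient RNA, doublets, or any
actual disease biology. Passing the recovery suites therefore
demonstrates that the statistical machinery is correct and calibrated
under its own assumptions — not that real tissue will yield any
particular rescue fraction.

## Problem sizes used in validation

The shipped suites use 5,000 genes at $n = 4$ per group for null
calibration, 800 genes (200 per class) at $n = 6$ for end-to-end rescue
recovery, 10,000 cells for composition recovery, 150 cells per group for
marker recovery, and 50 random toy instances against a brute-force
likelihood oracle — sizes chosen to keep Monte-Carlo error well below
the asserted tolerances while running in seconds.

## Known limitations

* Two-group contrasts only; no covariates, batch terms, or continuous
  designs.
* Moment + trend dispersion is simpler than the adaptive shrinkage of
  dedicated DE packages; at very small counts the test leans on the
  dispersion floor.
* The restoration-magnitude mean is sensitive to genes with small
  disease–control gaps just above the exclusion tolerance.
* Keyword curation is only as good as the set names; a lipid set with an
  uninformative name is invisible to it.
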