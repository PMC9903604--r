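---
title: "Classifying hybrid-parent triad expression patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hybrid-parent triad expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadexpress)
```

## The analysis in one paragraph

Given a gene × sample expression matrix for a maize hybrid (H) and its
maternal (M) and paternal (P) lines over developmental time points (days
after pollination, DAP), with biological replicates, the package asks of
every gene: does the hybrid express it additively (at the mid-parent value,
H ≈ ½(M + P)), with expression-level dominance (level with one parent while
the parents differ; ELD_M or ELD_P after the matched parent), or
transgressively (above or below both parents)? The answer is read off the
three pairwise differential-expression calls of the triad, and the
transcriptome-wide composition of answers — plus phenotype-side mid-parent
statistics — is the quantitative description of heterosis at that time
point.

## Differential expression

For a contrast between genotypes $a$ and $b$ at one DAP, each gene gets

* replicate means $\bar x_a$, $\bar x_b$ (FPKM),
* a fold change on the means with a pseudo-count,
  $\mathrm{log2fc} = \log_2\frac{\bar x_b + 1}{\bar x_a + 1}$ — the
  pseudo-count of one FPKM keeps zero-expression genes finite and damps
  ratios of very low expressors,
* a two-sided two-sample t-test on $\log_2(x+1)$ replicate values,
* Benjamini–Hochberg adjustment across the gene universe, and
* a call: **up** if $\mathrm{log2fc} \ge 1$ and $p_{adj} < \alpha$,
  **down** if $\mathrm{log2fc} \le -1$ and $p_{adj} < \alpha$, otherwise
  **ns**. The fold-change bound ($|FC| \ge 2$) is inclusive, the
  significance bound ($\alpha = 0.05$) strict.

**Why a pooled-variance t-test.** The three genotypes are the same tissue
sequenced on the same platform, so equal within-group variance on the log
scale is the natural assumption. More importantly, at $n = 3$ replicates
per group the Welch–Satterthwaite approximation is badly mis-calibrated:
simulation shows a type-I error of ≈ 0.035 at nominal 0.05 *even for
exactly normal data*, because the estimated degrees of freedom are both
noisy and upward-bounded by the tiny sample. The pooled Student t
($df = n_a + n_b - 2$) is exact under normality and, on simulated null
negative-binomial triads (the acceptance suite measures this on 10,000
null genes), stays within the two-sided 99% binomial band of the nominal
level. Welch remains available via `var_equal = FALSE`; it is used where
it belongs, in `mpv_significance()`, whose two samples have very unequal
sizes and variances by construction.

**Degenerate variances.** When both groups are constant the t statistic is
undefined; the package rules $p = 1$ for equal constants and $p = 0$ for
unequal ones. This matters only for all-zero count vectors in practice.

## The 13-class decision table

Write the three signed calls as $s_{mp} \in \{M{>}P,\, ns,\, M{<}P\}$,
$s_{mh} \in \{H{>}M,\, ns,\, H{<}M\}$, $s_{ph} \in \{H{>}P,\, ns,\,
H{<}P\}$. Of the 27 possible triples, exactly 13 are *directionally
consistent* named patterns, and the mapping is one-to-one
(`triad_class_table()`):

| category | classes | defining triple |
|---|---|---|
| transgressive up | 3 (by parental direction) | $H{>}M$ and $H{>}P$ |
| transgressive down | 3 | $H{<}M$ and $H{<}P$ |
| ELD_M | 2 (H ≈ M > P, H ≈ M < P) | $s_{mp} \ne ns$, $s_{mh} = ns$, $s_{ph}$ agreeing with $s_{mp}$ |
| ELD_P | 2 | $s_{mp} \ne ns$, $s_{ph} = ns$, $s_{mh}$ agreeing |
| additive intermediate | 2 | $M{>}H{>}P$ or $M{<}H{<}P$, all significant |
| additive conserved | 1 | all ns |

"≈" is operationalised as non-significance of the corresponding contrast —
no second equivalence test is run, matching field practice.

The remaining 14 triples are *conflicting*: no named pattern describes
them (e.g. the parents differ but the hybrid differs from neither, or the
hybrid differs from exactly one of two equal parents). Because published
classifications of this kind assign every gene a class, conflicts are
resolved by a **distance fallback**: the gene goes to the category whose
idealised reference is nearest to $\mu_H$ — the mid-parent
$\tfrac{\mu_M + \mu_P}{2}$ for additive, the matched parent for ELD — with
ties resolved towards additive (the conservative choice: additivity is the
null expectation). The fallback never assigns a transgressive class, since
a transgressive pattern requires both hybrid contrasts to be significant,
which makes the triple clean, not conflicting.

This bijective-table-plus-fallback construction was chosen over a
priority-ordered rule list because a priority list silently absorbs
conflicting triples into whichever dominance rule fires first, which
breaks a symmetry the classification must have: exchanging the M and P
inputs must map ELD_M ↔ ELD_P and preserve the additive and transgressive
categories. The test suite checks this label-swap symmetry on random call
tables, and checks the whole table against an independently coded rule
list over all 27 triples.

**Class numbering.** The canonical order is transgressive up ×3,
transgressive down ×3, ELD_M ×2, ELD_P ×2, additive intermediate ×2,
additive conserved (ids 1–13). Published tables of this classification are
not machine-readably numbered, so only category-level totals are
comparable across numberings; every derived percentage here depends only
on categories.

**Classification universe.** Genes expressed (replicate-mean FPKM ≥ 1) in
all three genotypes at the focal DAP. The 1-FPKM threshold is the field's
usual cut-off; it is a config key (`expressed_threshold`).

**Parent-level summary.** mid-parent = additive classes; high-parent =
transgressive up plus the ELD classes whose matched parent is the
higher-expressed one; low-parent = the mirror image.

## The simulator

No public generative model accompanies triad studies, so the simulator
uses the standard bulk RNA-seq model: per gene, a class drawn from a
mixture, a baseline $b \sim \mathrm{LogNormal}(\mu_{\log}, \sigma_{\log})$
in expression units, idealised genotype means from the class definition,
and negative-binomial counts with $\mathrm{Var} = \mu + \phi\mu^2$.

* **Class means** (`assign_class_means()`): "different" parents sit
  `effect_log2` apart symmetrically about the baseline
  ($b\,2^{\pm e/2}$); additive hybrids sit *exactly* at the arithmetic
  mid-parent; ELD hybrids equal the matched parent; transgressive hybrids
  sit `effect_log2` beyond the outer parent. With `effect_log2 = 0` every
  gene collapses to additive-conserved and is labelled as such.
* **Mixture default** (`default_class_proportions()`): the composition
  observed in a maize seed-coat triad at 3 DAP — 85.2% additive (73.7%
  parentally conserved), 6.1% ELD_M, 8.3% ELD_P, ~0.1% transgressive up,
  ~0.35% down.
* **Scaling**: expected counts are proportional to mean × transcript
  length (lengths uniform on 500–5000 bp), rescaled per genotype so each
  sample's expected total equals `library_size` (default 2×10⁷, a typical
  uniquely-mapped yield). An optional ±10% per-sample jitter
  (`library_jitter = 0.1`) exists to exercise normalisation.
* **Defaults**: 23,000 genes (the expressed fraction of an annotated maize
  genome), DAP grid {2,3,4,8,9,10}, 3 replicates, `effect_log2 = 2`
  (a four-fold parental split, comfortably beyond the |FC| ≥ 2 call
  threshold), `dispersion = 0.08`. The dispersion default is the one
  genuinely free knob: nothing public pins within-genotype biological
  variance, so it was set once so that replicate agreement lands in the
  regime a clean experiment reports (log-scale pairwise R² ≈ 0.93), and
  the acceptance script recomputes that statistic rather than assuming it.
* **Time points are independent**: a gene's class and means are shared
  across DAPs and only the NB noise differs. Real data have temporal
  trends; consequently simulated expressed-gene overlap across time points
  (~99%) is far higher than the ~75% of real seed-coat data, and passing
  overlap tests says nothing about temporal dynamics. FASTQ-level
  artefacts (mapping, GC, batch) are likewise not emulated.

The phenotype simulator draws logistic trait curves
$K / (1 + e^{-r(t - t_0)})$ per genotype over DAP 0–15 with truncated
Gaussian noise; defaults give the hybrid an asymptote above the mid-parent
value so the MPV test has something to find. The scales (K ≈ 70–92 mm²,
noise sd 3 mm²) are plausible seed-coat areas, chosen once for
realism, not fitted to anything.

## Phenotype statistics

* `mid_parent_value()` — $(m + p)/2$, the additive expectation.
* `relative_growth_rate()` — daily proportional increase of the trait
  mean, $(\bar x_t - \bar x_{t-1})/\bar x_{t-1}$; the classical
  log-difference RGR is available via `method = "log"` (for an exponential
  series the two give $e^r - 1$ and $r$). The successive-ratio form is the
  default because trait series here live on a daily integer grid.
* `mpv_significance()` — the hybrid replicates against a pseudo-MPV sample
  $\{(m_i + p_j)/2\}$ over parent replicate pairs (sorted, then capped at
  200 seeded draws so the cost is bounded and the result is
  parent-swap-invariant), Welch t. This reproduces the *direction* of
  published hybrid-vs-MPV tests; exact published p-values depend on the
  original replicate-level data.
* `cell_density()` — counts per 0.1 mm², the unit used for seed-coat
  sections.
* `ddct_relative_expression()` — Livak 2^−ΔΔCt with averaging on ΔCt
  before differencing, so the calibrator group reports exactly 1.

## Numerical conventions

* All reported percentages are `100 n / total` rounded **half-up** to two
  decimals (`pct()`); banker's rounding would disagree with published
  tables at exact .005 boundaries. Percentages of an empty denominator are
  `NA`, never 0/0.
* BH adjustment is delegated to `stats::p.adjust(method = "BH")` and
  verified against a hand-rolled step-up oracle to 10⁻¹².
* Replicate correlation is computed on $\log_2(x+1)$ by default (raw FPKM
  correlation is dominated by a few high expressors); zero-variance
  replicate pairs are excluded with a warning rather than propagating
  `NA`.
* Determinism: the simulator and pipeline are bit-identical given the
  spec/config seeds; every stochastic test fixes its seed.

## Known limitations

* **Exact mid-parent genes cannot yield the additive-intermediate call
  pattern.** If $\mu_H = (\mu_M + \mu_P)/2$ with parents $e$ log2-units
  apart, the hybrid-vs-nearer-parent ratio is
  $1 - \log_2(1 + 2^{-e}) < 1$ for every $e$, so the |FC| ≥ 2 leg of that
  contrast can never fire and such genes classify as ELD of the nearer
  parent (or conserved when nothing fires). This is a property of
  fold-change call-pattern classification itself, not of this
  implementation; it inflates ELD counts at the expense of
  additive-intermediate in any analysis of this design. Category-level
  composition remains close to the generating mixture because the reverse
  flow (underpowered ELD genes falling back to additive) largely cancels
  it, and 5-category recovery on strong effects (the acceptance suite
  measures ≥ 0.80 at `effect_log2 = 3`, dispersion 0.05) is unaffected in
  its conclusion.
* The DEG test has no dispersion shrinkage across genes; with 3 replicates
  its power is below a DESeq2-style analysis, which is visible as
  BH-marginal misses on low-expression genes. The classification consumes
  whatever calls it is given, so a count-model DEG backend can be swapped
  in upstream.
* Published headline DEG counts from real data depend on the original
  pipeline's test and cannot be reproduced from summary tables; the
  package therefore treats them as inputs to its summary arithmetic, not
  as targets.

## Problem sizes used by the test suite

Unit tests run on 20–2,000-gene fixtures; the stochastic properties use
20,000 genes (mixture goodness-of-fit), 10,000 (null calibration), 5,000
(class recovery), and the full-design pipeline run uses the 23,000-gene,
6-DAP, 3-replicate default — sizes chosen to match the study regime while
keeping the whole suite in a few seconds on one CPU.

```{r example}
spec <- triad_sim_spec(n_genes = 2000, daps = 3L, seed = 1)
sim <- simulate_triad_counts(spec)
fk <- fpkm(sim$counts, sim$gene_lengths)
universe <- Reduce(intersect, lapply(c("M", "H", "P"), function(g)
  expressed_genes(fk, g, 3)))
deg <- list(mp = deg_test(fk, "M", "P", 3, genes = universe),
            mh = deg_test(fk, "M", "H", 3, genes = universe),
            ph = deg_test(fk, "P", "H", 3, genes = universe))
patterns <- classify_triad(deg$mp, deg$mh, deg$ph)
summary(patterns)
class_recovery(sim$truth[sim$truth$gene_id %in% universe, ], patterns)$accuracy
```
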