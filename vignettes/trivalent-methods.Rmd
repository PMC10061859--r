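---
title: "Trivalent promoter analysis: models, parameters and design choices"
author: "trivalent package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trivalent promoter analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trivalent)
```

## The biological question and the procedure

Bivalent promoters carry both the active mark H3K4me3 and the repressive
mark H3K27me3 and sit poised between activation and silencing during
development. H3K4me1, usually thought of as an enhancer mark, is also
present at promoters in two distinct spatial configurations: a *typical
bimodal* pattern (high at the CpG-island shores, low over the island body)
at active promoters, and an *untypical*, body-high (unimodal) pattern at
bivalent promoters — which are therefore effectively *trivalent*. When a
cell state loses H3K27me3 at a bivalent promoter (during differentiation,
or artificially when PRC2 is inactivated), the H3K4me1 configuration
changes with it: some promoters lose their shore elevation (the
*bimodal-loss* group), others gain it (*bimodal-gain*). Because a body-high
H3K4me1 pattern behaves as a conditional repressor, the two groups respond
differently in expression, and the magnitude of the H3K4me1 change at
promoters and enhancers carries information about which genes become
tissue-specific.

The package decomposes this analysis into stages that mirror how it is run
on real ChIP-seq data:

1. **Promoter CGIs** (`define_promoter_cgis()`): CpG islands of 200–5000 bp
   overlapping a TSS ± 1 kb window, each linked to the gene with the
   nearest TSS.
2. **Signal matrices** (`bin_signal()`): per-mark, per-condition mean
   coverage in 20 bins over each 1 kb shore and 20 length-normalized bins
   over the island body.
3. **Three-class partition** (`kmeans_partition()`,
   `label_cluster_roles()`, `overlap_comparison()`): k-means (k = 3) on the
   concatenated standardized mark matrices; clusters are labelled
   low / bivalent / active from their mean H3K27me3 and H3K4me3 body
   signal, and partitions built from different mark pairs are compared by
   directional overlap of matching roles.
4. **Pattern and transition calls** (`classify_pattern()`,
   `call_transitions()`, `group_expression_contrast()`): two independent
   2-means splits (body and shore summaries) define the per-promoter
   H3K4me1 pattern; differencing the shore level between paired conditions
   defines the bimodal-loss / bimodal-gain groups, combined with a numeric
   H3K27me3-loss rule; group expression is contrasted with a Wilcoxon
   rank-sum test and a chi-squared test on up/down counts.
5. **Expression analysis** (`tau()`, `select_tissue_specific()`,
   `filter_de()`): the Tau specificity index, the two-criteria
   tissue-specific gene rule, and threshold filtering of a supplied
   differential-expression table.
6. **Association** (`build_design()`, `fit_logistic()`): logistic
   regression of tissue specificity on the condition deltas of promoter
   H3K4me1/H3K4me3/H3K27me3 and nearest-enhancer H3K4me1/H3K27ac.

`run_all()` composes the stages from one configuration and persists every
intermediate deterministically.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| CGI length bounds | 200–5000 | bp | definition of a promoter CGI; enforced everywhere |
| shore width | 1000 | bp | shores are defined as the adjacent 1 kb; fixed |
| `n_flank`, `n_body` | 20, 20 | bins | 50 bp shore bins resolve the bimodal shoulder while keeping matrices small; both are configuration knobs |
| `winsorize_pct` | 99 | percentile | clamps extreme promoters so they cannot dominate k-means distances |
| `k` | 3 | clusters | the low / bivalent / active partition; k ≥ 2 enforced |
| `loss_threshold` | derived | coverage | 50% of the condition-1 bivalent-cluster median body H3K27me3; an explicit numeric stand-in for "visible loss on a heatmap", needed for testability |
| DE thresholds | 2 / 0.05 and 1.2 / 0.1 | log2FC, p | the ESC-versus-tissue and wild-type-versus-knockout threshold pairs; both cuts inclusive |
| `top_rank`, `pct_threshold` | 5, 0.9 | rank, quantile | the two tissue-specificity criteria: tissue rank within gene at most 5, expression strictly above the within-tissue 90th percentile |
| enhancer distance | > 5000 | bp | H3K4me1 peaks further than 5 kb (midpoint to TSS) define enhancers; one nearest enhancer per gene |

## What the synthetic generator emulates — and what it does not

`make_genome()`, `make_tracks()` and `make_expression()` plant every piece
of structure the analysis is meant to recover, so each stage can be scored
against known labels. The deterministic coverage shape is a plateau at the
body amplitude over the CGI plus Gaussian shoulders (sd 250 bp) centred on
each shore; per-step (25 bp) counts are negative binomial around that
shape (size 10 by default), chosen because ChIP coverage is over-dispersed
relative to Poisson. The default conditions are: three equally sized
promoter classes; in the second condition every bivalent promoter drops
its H3K27me3 to baseline, 20% of bivalent promoters lose their H3K4me1
shore elevation (bimodal-loss) and a disjoint 20% gain it (bimodal-gain) —
at the 3,000-promoter validation scale that is 1,000 bivalent promoters
and 200 promoters per transition group. Six tissues carry five planted
tissue-specific (bivalent) genes each, and the knockout DE table plants
log2 fold changes of mean 0.5 (bimodal-loss) versus 2.0 (bimodal-gain)
with sd 0.3, so most bivalent genes are up-regulated but the bimodal-loss
group gains markedly less.

The expression background uses a discrete 10-level grid whose top level
carries 20% of the mass. This makes the within-tissue 90th percentile land
exactly on the top background level, so the strict "greater than"
comparison of the selection rule excludes every background gene and, in
the noiseless default, the recovered tissue-specific sets equal the
planted sets exactly — while the top-5 rank criterion still does real work
on the planted genes. With multiplicative noise enabled the recovery holds
only in expectation.

What the generator deliberately does **not** model: read-level artifacts
(mappability, duplicates, blacklist regions), nucleosome-scale structure,
many-to-many gene–promoter relations, fragment-length effects, diploid
genomes, or correlated noise between marks. Passing the validation suite
therefore demonstrates that the *algorithms* recover planted structure
under realistic count noise — not that any particular biological dataset
will show the same separability.

## Numerical choices

* **Coordinates** are BED-convention (0-based, half-open) on disk and in
  all interval tables; "TSS ± 1 kb" is `[tss − 1000, tss + 1000)`.
  Shores are genomic left/right, not strand-flipped: CGIs are unstranded,
  and flipping would only swap shore identity for minus-strand genes.
* **Binning** integrates the bedGraph step function exactly (cumulative
  integral with fractional endpoints), so body rescaling is exact
  fractional-bp averaging rather than nearest-bin resampling, binning is
  linear in the track, and the bp-resolution oracle agrees to 1e-9.
  Uncovered positions count as zero; negative input-adjusted values are
  clamped to zero. Chromosome-wide cumulative sums leave relative errors
  near machine precision (~1e-14), which is why "noiseless" sign tests use
  a 1e-6 dead-band.
* **k-means** uses squared-Euclidean Hartigan–Wong with 10 random restarts
  under a recorded seed, keeping the lowest within-cluster sum of squares;
  per-mark matrices are winsorized at the 99th percentile and column
  standardized first so no high-amplitude mark dominates. Constant feature
  matrices and role ties (deciding cluster means within 1e-9) are refused
  rather than broken arbitrarily.
* **Pattern mapping**: the 2 × 2 combination of body/shore levels maps
  body-high to `untypical_unimodal` regardless of shore level (body
  elevation dominates the poised signature), body-low/shore-high to
  `typical_bimodal`, and both-low to `flat`.
* **Logistic regression** is the ordinary binomial GLM (IRLS). Perfect or
  quasi-perfect separation and aliased predictors raise errors naming the
  offending predictor; no regularization is applied, so a failure is
  visible rather than silently shrunk. Confidence intervals are Wald,
  `exp(estimate ± 1.96 se)`. Predictors are standardized (centers and
  scales recorded) so odds ratios are comparable across marks.
* **Tests of group differences** report raw p-values (single headline
  tests per comparison, not a screen); the chi-squared test uses no
  continuity correction so it matches the closed form on 2 × 2 tables.

## Design decisions where the design was genuinely open

* The CGI-to-gene link uses the nearest overlapping TSS with lexicographic
  tie-breaking — a deterministic rule where several are defensible.
* "5 kb away from TSS" is measured enhancer-midpoint to TSS, symmetric
  with the nearest-enhancer assignment.
* The two 2-means clusterings behind the pattern call are run per
  condition and differenced, rather than jointly across conditions.
* The bimodal-loss/bimodal-gain groups are defined by the shore-level
  change alone; the transition *flag* additionally requires the H3K27me3
  loss. Continuous body and shore deltas are reported alongside so users
  can grade "lower unimodal" effects themselves.
* Cluster matching across partitions uses role identity (not a Hungarian
  assignment on counts), because partitions from different mark sets are
  compared through the meaning of their clusters.
* One logistic model is fit per focal tissue rather than pooling tissues
  with fixed effects.
* Confidence-interval coverage of the fit is validated pooled over the
  five coefficients (1,000 intervals across 200 replicates), which bounds
  the Monte-Carlo error of the coverage estimate below one point.

## Validation scale

The shipped test-suite and acceptance script exercise: 3,000-promoter
genomes (20 seeded replicates for partition recovery; one replicate for
pattern/transition recovery with 200 planted promoters per transition
group), 1,000-gene × 6-tissue expression matrices, 10,000 random intervals
against a quadratic promoter-definition oracle, 1,000 random vectors
against the direct Tau formula, and 200 replicates of n = 2,000 logistic
fits for bias, coverage and type-I error. These sizes were chosen so the
planted-subset counts match the conditions stated above while every
property remains measurable with small Monte-Carlo error.

## Known limitations

* Enhancer-region transition analysis reuses the same machinery on
  enhancer intervals; there is no bespoke enhancer model.
* The default loss threshold depends on the condition-1 bivalent cluster
  being identifiable; fully degenerate inputs require an explicit
  `loss_threshold`.
* Tissue-specific selection with few tissues makes the top-5 rank
  criterion weak (with six tissues, only the lowest-ranked tissue fails
  it); the percentile criterion then carries the selection, as it does in
  the noiseless synthetic construction.
* The logistic model assumes one promoter and at most one enhancer per
  gene; genes without an assigned enhancer are dropped (and counted).
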