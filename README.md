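# trivalent

Chromatin-state analysis of **trivalent promoters**: promoter CpG islands
(CGIs) that carry H3K4me1 on top of the classic bivalent pair
H3K4me3 + H3K27me3.

## The scientific problem

Bivalent promoters are poised between activation and silencing during
development. H3K4me1 — usually an enhancer mark — also occupies promoters,
in one of two spatial configurations over the CGI and its 1 kb shores:

* **typical bimodal** — shores high, body low (active promoters);
* **untypical / unimodal** — body high (bivalent promoters, which are
  therefore trivalent).

When a bivalent promoter loses H3K27me3 (differentiation, or PRC2
knockout), its H3K4me1 configuration shifts with it: the **bimodal-loss**
group loses shore H3K4me1, the **bimodal-gain** group acquires it. Because
body-high H3K4me1 acts as a conditional repressor, the two groups respond
differently in expression, and histone deltas at promoters and enhancers
predict which genes become tissue-specific.

The package implements that analysis for anyone with per-mark coverage
tracks, CGI/TSS annotation, an expression matrix and a DE table — and
ships a synthetic-data generator that plants every piece of ground truth,
so the whole pipeline is validated end to end against known labels.

## The statistics at its core

* Promoter CGIs: islands of 200–5000 bp overlapping TSS ± 1 kb.
* Signal matrices: exact mean coverage in 20 × 50 bp shore bins plus 20
  length-normalized body bins per promoter.
* Three-class partition: k-means (k = 3) on concatenated winsorized,
  column-standardized mark matrices; clusters labelled
  low / bivalent / active; partitions from different mark pairs compared
  by directional role overlap (|A∩B|/|A| and |A∩B|/|B|).
* Pattern calls: two 2-means splits (body, shore summaries) →
  typical_bimodal / untypical_unimodal / flat; transitions = shore-level
  change between paired conditions gated by an H3K27me3-loss rule.
* Tissue specificity: Tau index
  `τ = Σ(1 − x̂ᵢ)/(N − 1)`, `x̂ᵢ = xᵢ/max(x)`, on log2(x+1) medians; the
  two-criteria specific-gene rule (tissue rank ≤ 5 within gene, expression
  > within-tissue 90th percentile).
* Association: logistic regression (binomial GLM) of tissue specificity on
  Δ promoter H3K4me1/H3K4me3/H3K27me3 and Δ nearest-enhancer
  H3K4me1/H3K27ac, reported as odds ratios with Wald 95% CIs.

## Worked example

```r
library(trivalent)

cfg <- synthetic_config(n_promoters = 300, seed = 7)
report <- run_all(list(simulate = cfg))

report$objects$partition
#> cluster_assignment: 300 promoters, k = 3 (marks: H3K4me1, H3K4me3, H3K27me3)
#>   active bivalent      low
#>      100      100      100

table(report$objects$transitions$group)
#> bigain biloss   none
#>     20     20    260

report$objects$contrast
#> group_contrast: biloss n = 20 (median log2FC 0.481), bigain n = 20 (median log2FC 1.999)
#>   Wilcoxon p = 1.45e-11; chi-squared = NA (p = NA)

report$objects$fit
#> logistic_fit: n = 300, logLik = -11.34, converged in 11 iteration(s)
#>           term estimate    se odds_ratio ci_low ci_high p_value
#>   prom_H3K4me1   -0.193 0.319      0.824 0.4410    1.54  0.5449
#>   prom_H3K4me3    0.949 0.596      2.584 0.8032    8.31  0.1113
#>  prom_H3K27me3    1.592 2.446      4.914 0.0407  593.07  0.5150
#>    enh_H3K4me1    0.286 1.031      1.331 0.1763   10.05  0.7816
#>    enh_H3K27ac    2.764 1.506     15.864 0.8291  303.56  0.0664
```

Reading the output: the partition recovers the three planted 100-promoter
classes exactly; the 20 planted bimodal-loss and 20 bimodal-gain promoters
are found; the bimodal-loss group's expression gain (median log2FC 0.48)
is far below the bimodal-gain group's (2.0, Wilcoxon p ≈ 1e-11) — the
planted effect; the chi-squared is undefined here because no gene is
down-regulated at these planted means. In the logistic fit, enhancer
H3K27ac (planted to rise specifically at tissue-specific genes' enhancers)
carries the largest odds ratio.

With `run_all(config, outdir = "out")` every intermediate (BED, bedGraph,
TSV, JSON report) is persisted; re-running the same configuration
reproduces the files byte for byte.

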