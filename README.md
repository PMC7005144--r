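# enhancerRemodel

Analysis of **enhancer-landscape remodeling** between paired chromatin
states — for example a drug-sensitive parental cell line and its resistant
derivative — from ChIP-seq peak calls and signal tracks, together with
**Bliss-independence drug-synergy scoring** of combination viability
matrices. The package targets computational biologists studying how
resistant cells rewire distal regulatory elements (e.g. H3K27ac gains that
occur without BRD4 recruitment) and whether combination treatments that
attack both routes act synergistically.

## What it computes

Given gene annotations (BED6), peak calls (BED6/narrowPeak) and per-base
signal (bedGraph) for paired conditions:

1. **Regular enhancers** — peaks overlapping no gene body and strictly
   more than 5 kb from every gene body;
2. **Enhancer catalog** — merged regions × samples matrix of
   library-normalised signal (rpm and rpm/bp), plus a sample **PCA**
   (`log2(rpm+1)`, top-500 most-variable regions, region-centred, SVD);
3. **Super-enhancers** — enhancers ranked by increasing occupancy
   (rpm/bp); with both axes scaled to the unit square, the cutoff is the
   point where a slope-1 line is tangent to the ranked curve
   (found by exhaustive candidate search); enhancers strictly above the
   cutoff are super-enhancers;
4. **Remodeling classes** — per-region log2 fold changes of H3K27ac and
   BRD4 rpm (pseudocount 1), with threshold *t* = 1:
   `UNCHANGED` (|lfc_k27| < t), `LOST` (lfc_k27 ≤ −t),
   `GAINED_BRD4_DEPENDENT` (both ≥ t) and `GAINED_BRD4_INDEPENDENT`
   (lfc_k27 ≥ t, lfc_brd4 < t — H3K27ac up, BRD4 unchanged or down),
   plus distance-to-nearest-TSS summaries;
5. **Drug synergy** — Fraction Affected `FA = clamp(1 − treated/control, 0, 1)`,
   Bliss expectation `E = fa_a + fa_b − fa_a·fa_b` from measured
   single-agent margins, excess-over-Bliss per combination cell
   (> 0 synergy, < 0 antagonism), and IC50 by log-dose interpolation.

A synthetic-data generator (`simulate_genome()`,
`simulate_chip_experiment()`, `simulate_dose_matrix()`) plants remodeling
classes, heavy-tailed (Pareto) enhancer signal, negative-binomial counts
and additive drug interactions, so every stage is testable against known
ground truth.

## Worked example

The one-command demo generates a synthetic study (2,000 enhancer regions,
200 genes, paired H3K27ac/BRD4 experiments plus replicate H3K27ac tracks),
runs the whole pipeline on the written files and compares planted truth to
what was recovered:

```r
library(enhancerRemodel)
d <- run_demo(seed = 1)

summary(d$classes)
#> remodeling_table: 2000 regions (t = 1, pseudocount = 1)
#>   GAINED_BRD4_INDEPENDENT      90 (4.5%)
#>   GAINED_BRD4_DEPENDENT        49 (2.5%)
#>   LOST                        173 (8.7%)
#>   UNCHANGED                  1688 (84.4%)
#>   among differential: GAINED_BRD4_INDEPENDENT 28.8%, GAINED_BRD4_DEPENDENT 15.7%, LOST 55.4%

print(d$se_calls$k27_resistant)
#> se_call for sample 'k27_resistant': 139 / 2000 enhancers above the tangent cutoff
#>   cutoff at rank 1861, signal 0.8607 (rpm/bp)

print(d$bliss$planted)
#> bliss_result: 5 x 5 combination cells (epsilon = 0)
#>   verdicts: synergy 25, additivity 0, antagonism 0
#>   mean excess over combination cells: +0.1196
```

Reading the numbers: 93% of regions recover their planted class
(`d$recovery$accuracy`); the PCA places the three parental and three
resistant H3K27ac replicates on opposite signs of PC1 (59% of variance);
the heavy-tailed resistant sample yields 139 super-enhancers; the dose
matrix simulated with a planted +0.2 excess over Bliss is called synergy
in every combination cell, with mean excess 0.20 in unclipped cells; and
the planted 3-fold IC50 resistance shift is recovered as 2.94.

Individual stages are ordinary functions — `filter_regular_enhancers()`,
`merge_regions()`, `build_catalog()`, `pca_samples()`,
`call_super_enhancers()`, `classify_regions()`,
`distance_to_nearest_tss()`, `bliss_excess()`, `estimate_ic50()` — and
`run_remodeling_pipeline()` drives them from a declarative (list or YAML)
config, writing TSV outputs and an MD5 manifest so identical configs give
identical results. See `vignette("enhancer-remodeling")` for the methods
account, parameter meanings and limitations.

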