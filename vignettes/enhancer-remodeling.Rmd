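---
title: "Methods: enhancer remodeling analysis and drug-synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer remodeling analysis and drug-synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerRemodel)
```

## The problem

Tumour cells that become resistant to chromatin-targeted drugs frequently
remodel their enhancer landscape: distal regulatory regions gain or lose
the activity mark H3K27ac, and some gained enhancers recruit transcription
machinery without a corresponding gain of the BET-family reader BRD4.
Detecting that pattern from paired ChIP-seq of a parental and a resistant
cell state, and quantifying whether a drug combination that attacks both
the BRD4-dependent and the BRD4-independent routes is synergistic, requires
a small set of well-defined computations. This package implements them as
a pipeline over standard genomics file formats, together with a
synthetic-data generator that plants ground truth so every stage can be
validated end to end.

## The analysis model, stage by stage

### Regular enhancers and the signal catalog

Enhancer candidates enter as peak calls (BED6 or narrowPeak). A *regular
enhancer* is a peak that overlaps no annotated gene body and lies strictly
more than `min_gap` (default 5000) bp from every gene body on its
chromosome. The gap is measured edge-to-edge, the strict inequality is
deliberate (a peak at exactly 5 kb is removed), and "genic region" means
the annotated gene-body span with no promoter padding — the minimal
reading; padding can be emulated through `min_gap`. Peaks on chromosomes
without genes are retained, since the filter can only be evaluated against
the annotation it is given.

Filtered peaks from all samples are merged into a union of sorted,
non-overlapping regions (bookended intervals merge), and each sample's
per-base signal track (bedGraph) is quantified over each region:

- raw signal = sum of `value * overlap_length` over track intervals;
- `rpm = raw / library_total * 1e6`, where the library total is the
  track's full signal mass — so rpm is invariant to sequencing depth;
- optional background subtraction of a control track, clipped at 0,
  because negative occupancy has no physical meaning;
- `rpm_per_bp = rpm / region_length`, the density used for
  super-enhancer ranking.

Normalisation is deliberately plain per-million scaling. Quantile or
spike-in normalisation is out of scope; the consequence (a compositional
bias when the two libraries differ in total differential signal) is
discussed under *Known limitations*.

### Enhancer-landscape PCA

`pca_samples()` transforms the rpm matrix as `log2(rpm + 1)`, keeps the
`top_k = 500` most variable regions, centres each region across samples
(no scaling), and projects samples by SVD — the behaviour of the standard
regularised-log PCA plot used for sample-level QC of count matrices.
Variance fractions are reported relative to the total variance of the
selected, centred matrix. Whether such a PCA is best run on rpm or rpm/bp
is not a settled convention; rpm is the default here and `top_k` is
exposed, since both choices only reweight regions, not samples.

### Super-enhancer calling: the tangent cutoff

Enhancers are ranked by increasing background-subtracted occupancy in
rpm/bp. On axes scaled to the unit square, the cutoff is the point where a
line of slope 1 is tangent to the ranked curve; in rank/signal units that
slope is `m = (max - min) / n`. The implementation tries *every* rank `i`
as the tangent point: it draws the slope-`m` line through `(i, s[i])` and
counts the points of the curve lying on or below it; the tangent point
minimises that count (smallest rank on ties), and enhancers strictly above
the cutoff signal are super-enhancers. Exhaustive search was chosen over
numeric optimisation deliberately: it is deterministic, O(n²) is
negligible at catalogue sizes, and it cannot stall in the local optima
that golden-section-style searches are prone to on staircase-like curves.

Numerical detail: the "on or below the line" comparison uses a tolerance
of `1e-9` times the signal range. Without it, floating-point rounding can
make a candidate point fall a few ulps below its own tangent line, which
makes the selected rank depend on the overall scale of the data; with the
range-proportional tolerance the cutoff is exactly invariant under
positive rescaling. Degenerate cases: a flat curve has slope 0, cutoff at
rank 1, and hence zero super-enhancers (nothing is strictly above);
a single enhancer is its own cutoff.

Peak stitching (joining nearby peaks before ranking) is intentionally not
performed: the ranked-tangent definition is complete without it, and the
package does not silently add steps. Merging adjacent regions before
catalog construction achieves the same effect explicitly.

### Remodeling classification

For paired conditions, per-region log2 fold changes of H3K27ac and BRD4
rpm are computed as `log2((a + pc) / (b + pc))` with pseudocount `pc = 1`
rpm. With threshold `t = 1` (log2 units):

| condition | class |
|---|---|
| `|lfc_k27| < t` | UNCHANGED |
| `lfc_k27 <= -t` | LOST |
| `lfc_k27 >= t` and `lfc_brd4 >= t` | GAINED_BRD4_DEPENDENT |
| `lfc_k27 >= t` and `lfc_brd4 < t` | GAINED_BRD4_INDEPENDENT |

"BRD4 unchanged or decreased" is encoded as *not gained* (`lfc_brd4 < t`),
one rule covering both cases, which is exactly what a red-box quadrant
covering "no change or decreased" pools together. Classification is a
threshold rule rather than a count-based test because the design this
addresses has one track per condition and mark: without replicates there
is no dispersion to estimate, and any p-value would be decorative. Both
`t` and the pseudocount are exposed. The rule is antisymmetric: swapping
the conditions negates both fold changes and maps gains onto losses.

Distances from classified regions to promoters use the region midpoint
(`floor((start + end) / 2)`) to the nearest same-chromosome TSS, where the
TSS of a minus-strand gene is `end - 1` in half-open coordinates. Midpoint
to TSS was chosen over edge-to-gene-body because the quantity of interest
is "how far is this element from the promoter it may regulate"; the
gene-body gap is already what the regular-enhancer filter measures.
Regions on chromosomes with no annotated gene have no defined distance and
are counted separately, never dropped silently. Histogram bins are fixed
10-kb bins anchored at 0.

### Drug-combination synergy

Fraction Affected is `FA = clamp(1 - treated/control, 0, 1)` — the
standard viability-assay convention and the only monotone choice keeping
FA a fraction. For a dose grid with mandatory zero row/column, the Bliss
independence expectation for each combination cell is
`E = fa_a + fa_b - fa_a * fa_b` computed from the *measured* single-agent
margins (no curve smoothing first), and the excess is `fa - E`: positive
excess is synergy, negative antagonism, with an optional dead-band
`epsilon` (default 0, the plain sign rule) for noise-aware verdicts.
When replicate matrices exist they should be averaged before scoring;
per-replicate excess remains available by scoring each matrix.

IC50 is estimated by linear interpolation of FA against log dose after an
isotonic (monotone non-decreasing) cleanup, with exact grid hits returned
exactly and a not-reached flag when FA never brackets 0.5. Four-parameter
logistic fitting is deliberately out of scope: on 5–7 point screens,
log-linear interpolation is assumption-light, deterministic, and accurate
to a few percent against exact Hill curves (the package's tests quantify
this on a planted 3-fold shift).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
study conditions for all recovery claims.

**Genome layout.** Features (gene bodies 2–10 kb, enhancers 0.5–2 kb) are
placed in randomly shuffled, margin-padded slots so that genes never
overlap and every enhancer clears the >5 kb regular-enhancer filter by
construction. Optional distractor peaks placed inside gene bodies exercise
the filter. If the requested features cannot fit, placement fails loudly.

**Signal model.** Each region's expected parental count is a Pareto draw
with mean `base_mean = 100` and shape 3 by default: heavy-tailed enough
that the ranked curve is a hockey stick (a minority of regions carries a
large share of signal, which is the regime where a tangent cutoff is
meaningful), while keeping finite variance so library totals are stable
across seeds. Shape is exposed; analyses that want an extreme tail (e.g.
stress-testing the super-enhancer caller) pass shape 1.5. Observed counts
are negative-binomial with dispersion 0.05 by default — ChIP material is
overdispersed relative to Poisson, and dispersion is the difficulty dial;
dispersion 0 gives deterministic counts for exact limit tests. Counts are
spread uniformly over each region into a bedGraph track, with a constant
background between regions at 1% of the mean per-bp region density so that
library totals (and hence rpm) are exercised honestly.

**Planted classes.** Default proportions are UNCHANGED 0.90,
GAINED_BRD4_INDEPENDENT 0.04, GAINED_BRD4_DEPENDENT 0.03, LOST 0.03, with
planted |lfc| = 2. Differential regions are a deliberate minority: rpm
normalisation is only approximately unbiased when differential signal is
a small share of the library (see limitations), and genome-wide paired
comparisons are dominated by unchanged regions. The BRD4 fold change of
the BRD4-independent gained class is uniform on [-1.5, 0] — "no change or
decreased" without making recovery trivial. The planted effect size is a
calibration choice, not an empirical fact about any particular dataset.

**Dose matrices.** Single agents follow Hill curves
`fa(d) = d^h / (d^h + IC50^h)` on geometric dose grids (ratio 4)
bracketing each IC50; combination cells equal the Bliss expectation plus
an additive interaction term plus optional Gaussian noise, clipped to
[0, 1] (FA is a fraction by definition; clipping happens after noise).
With interaction 0 and noise 0 the generated matrix satisfies Bliss
independence *exactly*, by construction — the scored excess is identically
zero to machine precision, which pins down the sign conventions of the
whole synergy module.

**What the generator does not emulate.** Read-level artefacts (GC bias,
duplicates, fragment-length effects), peak-calling uncertainty (truth
regions are used as peaks), replicate correlation beyond shared means,
and realistic inter-chromosomal structure. Passing recovery tests on this
generator therefore demonstrates that the *computations* are correct and
well-calibrated under the stated statistical model — not that any
particular biological dataset will reach the same accuracy.

## Pipeline, determinism and problem sizes

`run_remodeling_pipeline()` composes the stages from a declarative config
(list or YAML), writes every tabular output as TSV, and records a manifest
of MD5 content hashes plus parameters; identical configs give identical
hashes. Every simulation function takes an explicit seed and restores the
caller's RNG state, so end-to-end runs are reproducible bit for bit.
`run_demo()` generates a full synthetic study — 2,000 enhancer regions and
200 genes on a 40-Mb chromosome, four paired ChIP experiments plus two
extra H3K27ac replicates per condition for a 3 + 3 PCA, and the synergy
matrices — runs the pipeline on the written files, and reports planted
truth against recovery. These sizes keep a complete run in the tens of
seconds on a laptop while leaving each class with enough regions for
stable fractions; they scale up linearly if larger studies are wanted.

## Known limitations

- **rpm compositional bias.** When gained regions add more signal to the
  resistant library than lost regions remove, per-million scaling deflates
  every resistant fold change by the library-ratio log2 (about 0.2–0.3
  under the generator defaults). The default threshold `t = 1` with
  planted |lfc| = 2 absorbs this, and recovery stays above 90%, but the
  bias is visible as an excess of UNCHANGED regions drifting into LOST.
  Median-of-ratios or unchanged-region anchoring would remove it and is a
  natural extension; it is not part of the present scope.
- **Single-track conditions.** The threshold classifier makes no error
  claim per region; with replicated designs a count-based test would be
  preferable.
- **Tangent cutoff granularity.** On very small catalogues (tens of
  regions) the tangent rank is coarse; the cutoff is still well-defined
  but a one-rank shift can move several regions across the boundary.
- **IC50 interpolation** assumes the response brackets 0.5 inside the dose
  range; it reports not-reached rather than extrapolating.
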