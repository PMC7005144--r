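Package: enhancerRemodel
Title: Enhancer Remodeling Analysis and Bliss Drug-Synergy Scoring for
    Paired ChIP-seq Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse enhancer-landscape remodeling between paired
    chromatin states (for example parental versus drug-resistant leukemia
    cells) from peak calls and per-base signal tracks: regular-enhancer
    filtering against gene annotations, cross-sample region merging,
    library-normalised (rpm and rpm/bp) signal-matrix construction,
    principal-component analysis of enhancer landscapes, super-enhancer
    identification by the ranked-signal tangent cutoff, paired differential
    H3K27ac/BRD4 quadrant classification with distance-to-promoter
    summaries, and Bliss-independence excess scoring of drug-combination
    viability matrices with log-dose IC50 interpolation. A synthetic-data
    generator plants remodeling classes, heavy-tailed enhancer signal and
    drug-interaction terms so every stage can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
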