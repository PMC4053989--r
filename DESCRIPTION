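Package: crmscan
Title: Conserved-Motif Scanning and Enhancer Prediction for
    Transcription-Factor Target Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps a transcription factor's direct-target enhancers from
    sequence, peak, and expression evidence. Implements phylogenetic
    footprinting of binding sites (position weight matrix scanning of
    orthologous sequence sets with alignment-free conservation support),
    a 1-kb binding-site clustering rule, discriminative de novo motif
    discovery between validated enhancers and inactive regions with
    binomial over-representation and Pareto ranking, motif/ChIP-peak
    cross-correlation with a chi-squared test, nearest-TSS peak-to-gene
    assignment, a two-mutant expression filter defining the regulated
    gene set, motif-based gene ranking with recovery-curve analysis
    against randomized gene sets, and combinatorial enhancer prediction
    with per-species architecture reports. A seeded synthetic-data
    generator emits multi-species ortholog sets with planted motif
    instances and decoys, peaks, TSS tables and a replicated expression
    matrix together with a ground-truth manifest, so the whole pipeline
    is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
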