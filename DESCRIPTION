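Package: wildvar
Title: Downstream Variant Analysis for Wild Rice Re-Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-calling analysis of small variants from high-depth plant
    re-sequencing panels against a reference genome. Implements positional
    and depth-window variant filters, transition/transversion and
    zygosity summaries, insertion/deletion length spectra, 100-kb windowed
    variant-density scans with boxplot-outlier calling of variation-rich
    and variation-poor regions, codon- and splice-aware large-effect
    classification of variants against gene models, non-synonymous to
    synonymous ratios per protein domain family, detection of
    resistance-gene clusters, and read-coverage based presence/absence
    calls over pan-genome unique genes. Ships a deterministic synthetic
    data generator (genome, gene models, multi-sample variant sets, depth
    tracks) with recorded ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
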