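Package: marsil
Title: Silencer Integrity and Chromatin Status of mariner Transposon Loci
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-scale analysis of the silencer element carried by
    mariner-like DNA transposons. Assembles RepeatMasker alignment fragments
    into element loci, classifies each copy by the integrity of its Delta8
    silencer segment (Sil+/Sil-/U) and by genic or intergenic location, calls
    a per-cell-line chromatin status (Polycomb, Trithorax, Su(var)39/HP1 or
    undetermined) from ChIP-seq peak co-localization, scans consensus and
    genomic copies for YY1 profile and NFAT-5 literal binding motifs, and
    tests silencer/Polycomb associations with paired Wilcoxon signed-rank and
    Student t tests. Ships a seeded synthetic-data generator that emits a
    complete input bundle (genome, genes, repeat annotation, per-cell-line
    peaks) together with a ground-truth manifest for recovery and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
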