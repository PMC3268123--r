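Package: draftcompare
Title: Comparison and Experimental Disambiguation of Alternate Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies structural discordances between two
    alternate assemblies of the same genome (inversions, segments mapped in
    distinct positions, one-draft-only sequences, and discordant chromosome
    assignments), places one draft's unassigned scaffolds onto the other
    draft's chromosomes, designs BAC-end-sequence based probe panels and
    junction long-PCR assays to test each discordance, and decides between
    the two assemblies with simulated metaphase/interphase FISH and in
    silico PCR read-outs. Ships a synthetic-genome rearrangement simulator
    with machine-readable truth tables so the whole pipeline is exercisable
    end to end at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
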