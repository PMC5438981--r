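Package: plastrep
Title: Comparative Plastome Architecture and Repeat-Origin Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structural comparative analysis of chloroplast genomes:
    detection of the inverted-repeat pair and quadripartite
    (LSC/IRb/SSC/IRa) partitioning, mapping of IR junctions to their gene
    context, five-state integrity typing of the rps16 locus with an
    in-silico PCR section marker, profiling of the rpl23-ycf2 intergenic
    spacer (trnI_CAU copy number, tandem repeats, conserved motifs), and
    rule-based classification of slipped-strand-mispairing repeat-origin
    scenarios. Includes a synthetic plastome generator that plants fully
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
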