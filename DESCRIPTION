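Package: intronevo
Title: Intron Position Evolution: Simulation, Splice-Site Homology, and
    Parsimony Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of protein-coding gene structure across
    species: derives intron positions in protein coordinates from GFF3 gene
    models, projects them onto protein multiple sequence alignments to define
    homologous splice-site characters, reconstructs intron gains and losses on
    a rooted species tree by weighted (Sankoff) parsimony with exhaustive
    enumeration of equally parsimonious scenarios (reported as per-branch
    ranges), and computes robust exon- and protein-size summaries with
    stratified ortholog sampling. Includes a generative simulator of intron
    presence/absence evolution that emits internally consistent GFF3, FASTA
    and alignment files with a known event history, so every stage of the
    pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
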