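Package: MEst
Title: Parental-Origin Placement of Polyploid Alleles on a Diploid
    Backbone Tree by Balanced Minimum Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the diploid parental origin of individual alleles from
    allopolyploid accessions. Each polyploid allele is placed onto a fixed
    diploid backbone species tree by grafting it onto every backbone edge
    and scoring each candidate with the balanced minimum evolution
    criterion (Pauplin weights) applied to NJst internode distances
    averaged over discordant gene trees. Placements over bootstrap
    gene-tree replicates are summarized as per-edge and per-clade
    supports, median allele counts, and trimmed 90 percent confidence
    intervals. Includes a multispecies-coalescent simulator that plants
    polyploid alleles on known donor edges for validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
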