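Package: rnagrowthlaw
Title: An Optimal Growth Law for Cellular RNA Composition and Its Genomic
    Implementation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the growth-rate dependence of the tRNA/rRNA (ternary
    complex per ribosome) expression ratio as the analytic minimum of the
    combined ribosome plus ternary-complex mass density at a fixed protein
    synthesis flux, and its partial genomic implementation through
    replication-associated gene dosage of tRNA and rRNA genes positioned
    relative to the origin of replication. Includes Cooper-Helmstetter gene
    dosage, oriC-relative gene positioning from GFF3 or GenBank annotations,
    single-parameter fitting of the ribosomal turnover number to expression
    data, phylogenetically independent contrasts, and a synthetic-data
    generator (genomes, expression ratios, trees with Brownian traits) so
    the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
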