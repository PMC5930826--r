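Package: pancocci
Title: Pan-Genome, Core-Genome and Amino-Acid Identity Analysis for
    Cocci-Shaped Sporosarcina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics pipeline for closely related bacterial
    strains, built around the cocci-shaped Sporosarcina study system:
    all-vs-all Smith-Waterman protein similarity with BLAST-style
    identity/coverage/E-value statistics, threshold-based single-linkage
    ortholog clustering into core, accessory and strain-specific gene
    sets, ordered core-gene concatenation, average amino-acid identity
    (AAI) and fragment-based average nucleotide identity (ANI) matrices,
    species delimitation at a 95 percent AAI cutoff, neighbor-joining
    trees from core-gene, gene-content and AAI distances, a
    reference-gene presence screen, and a seeded simulator of proteome
    families with planted clade structure for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
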