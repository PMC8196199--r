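Package: sseanatomy
Title: Secondary Structure Anatomy of Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the "anatomy" of a protein family from per-domain
    secondary structure element (SSE) annotations: occurrence frequencies
    with Agresti-Coull confidence intervals, length distributions,
    end-gap-only multiple sequence alignment (no internal gaps) scored with
    a substitution matrix, sequence-logo information content and
    conservation, selection of reference residues and assignment of
    @X.50-anchored generic residue numbers, statistical comparison of
    taxonomic subgroups, offline dataset curation (non-redundant selection,
    superkingdom split, template selection from a similarity matrix), and a
    seeded synthetic-family generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
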