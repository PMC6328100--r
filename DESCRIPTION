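Package: flat2webin
Title: Convert Annotated EMBL and GenBank Flat Files into ENA Webin
    Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts multi-record EMBL- or GenBank-formatted flat files of
    common plant and fungal DNA-barcoding markers (gene introns, intergenic
    spacers, the plastid trnK/matK region, nuclear ribosomal rDNA, ITS and
    ETS) into submission-ready, tab-delimited checklists for the interactive
    Webin submission system of the European Nucleotide Archive (ENA). Each
    checklist type carries its own column schema; records are audited per
    marker (mismatched checklist selections abort the run, missing feature
    prerequisites skip the record), feature and qualifier spellings are
    checked against a bundled INSDC vocabulary, and intron coordinates and
    feature completeness are derived from feature locations rather than
    qualifier text. A seeded fixture generator produces dummy flat files
    with ground-truth manifests for testing every conversion path without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
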