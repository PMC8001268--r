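Package: varledger
Title: Lifecycle Management of Clinical Sequence Variants Across
    Annotation Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deduplicated store for clinical sequence variants with
    historically tracked attribute values. Heterogeneous VCF dialects and
    delimited annotation or classification files are ingested under
    declarative dialect specifications (field-to-attribute mappings, row
    filters, break conditions, derived attributes such as allele frequency
    from allelic and read depth). Imports can be restricted to virtual
    gene panels for informed-consent compliance. Unique variants can be
    exported as chunked VCF files inside a ZIP archive for external
    re-annotation, and change-detection queries over attribute histories
    surface reclassified variants (for example ClinVar transitions from
    benign or uncertain significance to pathogenic) together with the
    samples that carry them. Includes deterministic synthetic generators
    for both VCF dialects and for annotation and classification files,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
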