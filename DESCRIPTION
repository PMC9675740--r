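Package: prefixkit
Title: Standardization, Alignment, and Export of Biomedical Identifier
    Prefix Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for maintaining a registry of biomedical identifier
    resources and using it as an interoperability layer. Provides a
    validated tabular data model for identifier-resource records (canonical
    prefix, synonyms, identifier pattern, URI format strings, providers,
    deprecation, attribution), a standardization engine for prefixes,
    CURIEs, and URIs (normalization, redundant-namespace stripping,
    identifier pattern validation, URI expansion and contraction), a
    multi-registry alignment algorithm that produces cross-registry
    equivalence mappings under per-registry import policies, exporters to
    prefix-map contexts (JSON-LD), SSSOM mapping tables, RDF
    (N-Triples/Turtle/JSON-LD), and TSV, a CURIE resolver with a
    stub-injectable health report, and a seeded synthetic-fixture generator
    with planted ground truth for testing alignment recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
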