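test_that("export_context maps eligible records to URI prefixes and applies exclusions", {
  reg <- example_registry()
  ctx <- export_context(reg)
  expect_identical(ctx$uri_prefix[ctx$prefix == "chebi"],
                   "http://purl.obolibrary.org/obo/CHEBI_")
  expect_false("hgnc.genefamily" %in% ctx$prefix) # deprecated records are excluded

  nonterminal <- dplyr::bind_rows(
    reg,
    new_record("mid", name = "x", homepage = "h", description = "d",
               uri_format = "https://x.org/$1/view")
  )
  expect_warning(ctx2 <- export_context(nonterminal), "not terminal")
  expect_false("mid" %in% ctx2$prefix)

  obo <- export_context(reg, profile = "obo")
  expect_true("CHEBI" %in% obo$prefix)   # preferred casing
  expect_true("hgnc.genegroup" %in% obo$prefix) # no preferred prefix: canonical

  sub <- export_context(reg, collection = c("go", "chebi"))
  expect_setequal(sub$prefix, c("go", "chebi"))
})

test_that("URI-prefix collisions in a context follow the configured policy", {
  clash <- dplyr::bind_rows(
    new_record("one", name = "x", homepage = "h", description = "d",
               uri_format = "https://same.org/$1"),
    new_record("two", name = "x", homepage = "h", description = "d",
               uri_format = "https://same.org/$1")
  )
  expect_error(export_context(clash, strict = TRUE), class = "prefixkit_collision_error")
  expect_warning(kept <- export_context(clash), "collision")
  expect_identical(kept$prefix, "one") # first in prefix order wins
})

test_that("every context entry parses back to its own prefix", {
  reg <- example_registry()
  ctx <- export_context(reg)
  probe <- paste0(ctx$uri_prefix, "12345")
  back <- parse_uri(reg, probe)
  expect_identical(back$prefix, ctx$prefix)
  expect_setequal(back$luid, "12345")
})

test_that("SSSOM export has one row per cross-registry mapping", {
  reg <- example_registry()
  doc <- export_sssom(reg)
  expect_identical(nrow(doc$rows), nrow(registry_mapping_table(reg)))
  expect_setequal(unique(doc$rows$predicate_id), "skos:exactMatch")

  expect_identical(nrow(export_sssom(empty_registry())$rows), 0L)

  many <- new_record("busy", name = "x", homepage = "h", description = "d",
                     mappings = tibble::tibble(
                       registry_key = paste0("r", 1:7), external_prefix = paste0("P", 1:7)
                     ))
  expect_identical(nrow(export_sssom(many)$rows), 7L)
  expect_identical(export_sssom(many)$rows$object_id, paste0("r", 1:7, ":P", 1:7))
})

test_that("SSSOM TSV round-trips through its commented YAML header", {
  reg <- example_registry()
  doc <- export_sssom(reg)
  path <- withr::local_tempfile(fileext = ".sssom.tsv")
  write_sssom(doc, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines[1:3], "# ")))
  back <- read_sssom(path)
  expect_identical(back$rows, doc$rows)
  expect_identical(back$metadata$license, doc$metadata$license)
})

test_that("RDF serializations carry the identical triple set in all three syntaxes", {
  reg <- example_registry()
  reference <- registry_triples(reg)
  for (syntax in c("ntriples", "turtle", "jsonld")) {
    parsed <- parse_rdf(export_rdf(reg, syntax), syntax)
    expect_identical(
      dplyr::arrange(parsed, s, p, o_type, o),
      dplyr::arrange(reference, s, p, o_type, o),
      info = syntax
    )
  }
  expect_error(export_rdf(reg, "rdfxml"), class = "prefixkit_config_error")
})

test_that("the RDF export covers required metadata, dependencies, and the bare schema", {
  reg <- example_registry()
  tr <- registry_triples(reg)
  rdfs_label <- "http://www.w3.org/2000/01/rdf-schema#label"
  dct_desc <- "http://purl.org/dc/terms/description"
  subjects <- paste0("https://w3id.org/prefixkit/resource/", reg$prefix)
  for (s in subjects) {
    expect_true(any(tr$s == s & tr$p == rdfs_label), info = s)
    expect_true(any(tr$s == s & tr$p == dct_desc), info = s)
  }
  dep <- tr[tr$p == "https://w3id.org/prefixkit/schema#dependsOn" & tr$o_type == "iri", ]
  dep <- dep[dep$s %in% subjects, ]
  expect_identical(nrow(dep), sum(lengths(reg$depends_on))) # one triple per target

  bare <- registry_triples(empty_registry())
  expect_gt(nrow(bare), 0L) # schema-only triples remain
  expect_true(all(grepl("w3id.org/prefixkit/schema", bare$s)))
})

test_that("TSV export is flat, pipe-joined, and round-trips scalar fields", {
  reg <- tiny_registry()
  flat <- export_tsv(reg)
  expect_identical(nrow(flat), nrow(reg))
  expect_identical(flat$synonyms[flat$prefix == "alpha"], "alpha-db|adb")
  expect_identical(flat$mappings[flat$prefix == "alpha"], "extreg:ALPHA")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry_tsv(reg, path)
  raw <- readBin(path, "raw", file.size(path))
  expect_false(any(raw == charToRaw("\r"))) # LF endings only
  back <- read_registry_tsv(path)
  for (f in c("prefix", "preferred_prefix", "name", "homepage", "description",
              "pattern", "example", "uri_format", "deprecated", "proprietary",
              "replaced_by", "license", "version", "contact")) {
    expect_identical(back[[f]], reg[[f]], info = f)
  }
  expect_identical(back$synonyms, reg$synonyms)
  expect_identical(back$depends_on, reg$depends_on)
})

test_that("all exporters are byte-deterministic", {
  reg <- example_registry()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_context(export_context(reg), p1); write_context(export_context(reg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  write_sssom(export_sssom(reg), p1); write_sssom(export_sssom(reg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_identical(export_rdf(reg, "turtle"), export_rdf(reg, "turtle"))
  expect_identical(export_rdf(reg, "jsonld"), export_rdf(reg, "jsonld"))
})
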