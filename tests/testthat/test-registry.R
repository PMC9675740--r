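test_that("validate_record accepts a well-formed record and reports broken invariants", {
  good <- new_record("go", name = "Gene Ontology", homepage = "http://geneontology.org",
                     description = "x", pattern = "^\\d{7}$", example = "0006915",
                     uri_format = "http://purl.obolibrary.org/obo/GO_$1")
  expect_identical(nrow(validate_record(good)), 0L)

  prefixed_example <- dplyr::mutate(good, example = "GO:0006915")
  v <- validate_record(prefixed_example)
  expect_identical(v$check, "pattern-mismatch")

  no_placeholder <- dplyr::mutate(good, uri_format = "http://x.org/id/")
  expect_identical(validate_record(no_placeholder)$check, "placeholder")

  two_placeholders <- dplyr::mutate(good, uri_format = "http://x.org/$1/$1")
  expect_identical(validate_record(two_placeholders)$check, "placeholder")
})

test_that("validate_record enforces prefix shape, synonym distinctness, and deprecation rules", {
  bad_prefix <- new_record("GO!", name = "x", homepage = "h", description = "d")
  expect_true("prefix-shape" %in% validate_record(bad_prefix)$check)

  self_syn <- new_record("go", name = "x", homepage = "h", description = "d",
                         synonyms = c("go", "gont"))
  expect_true("prefix-in-synonyms" %in% validate_record(self_syn)$check)

  dup_syn <- new_record("go", name = "x", homepage = "h", description = "d",
                        synonyms = c("g-o", "g.o"))
  expect_true("synonym-collision" %in% validate_record(dup_syn)$check)

  undeprecated <- new_record("old", name = "x", homepage = "h", description = "d",
                             replaced_by = "new")
  expect_true("replaced-not-deprecated" %in% validate_record(undeprecated)$check)

  # deprecated records only need name + description
  deprecated_ok <- new_record("old", name = "x", description = "d",
                              deprecated = TRUE, replaced_by = "new")
  expect_false("required-field" %in% validate_record(deprecated_ok)$check)
  live_missing <- new_record("live", name = "x", description = "d")
  expect_true("required-field" %in% validate_record(live_missing)$check)

  bad_orcid <- new_record("go", name = "x", homepage = "h", description = "d",
                          contributor = attribution("A", "1234-5678"))
  expect_true("orcid-shape" %in% validate_record(bad_orcid)$check)
  good_orcid <- new_record("go", name = "x", homepage = "h", description = "d",
                           contributor = attribution("A", "0000-0002-1825-0097"))
  expect_identical(nrow(validate_record(good_orcid)), 0L)
})

test_that("registry-level QA detects cross-record key collisions and mapping duplicates", {
  expect_identical(nrow(validate_registry(tiny_registry())), 0L)

  v <- validate_registry(collision_registry())
  expect_true("lookup-collision" %in% v$check)

  shared_mapping <- dplyr::bind_rows(
    new_record("a", name = "x", homepage = "h", description = "d",
               mappings = tibble::tibble(registry_key = "r", external_prefix = "X")),
    new_record("b", name = "x", homepage = "h", description = "d",
               mappings = tibble::tibble(registry_key = "r", external_prefix = "X"))
  )
  expect_true("mapping-collision" %in% validate_registry(shared_mapping)$check)

  dangling <- new_record("a", name = "x", homepage = "h", description = "d",
                         deprecated = TRUE, replaced_by = "ghost")
  expect_true("dangling-reference" %in% validate_registry(dangling)$check)
})

test_that("collections must reference existing prefixes", {
  reg <- tiny_registry()
  ok <- collection("c1", "Test collection", members = c("alpha", "beta"))
  expect_identical(nrow(validate_registry(reg, collections = ok)), 0L)
  bad <- collection("c2", "Broken", members = c("alpha", "ghost"))
  expect_true("collection-member" %in% validate_registry(reg, collections = bad)$check)
})

test_that("merge_external_metadata fills only empty fields and is idempotent", {
  rec <- new_record("alpha", name = "Alpha Resource", homepage = "https://alpha.example.org",
                    description = "d",
                    mappings = tibble::tibble(registry_key = "extreg", external_prefix = "ALPHA"))
  ext <- external_record("extreg", "ALPHA", name = "alpha (external)", pattern = "^\\d+$")

  merged <- merge_external_metadata(rec, ext)
  expect_identical(merged$pattern, "^\\d+$")      # empty field gained
  expect_identical(merged$name, "Alpha Resource") # curated content wins
  expect_identical(merge_external_metadata(merged, ext), merged)

  expect_identical(nrow(validate_record(merged)), 0L)

  unmapped <- external_record("otherreg", "ALPHA", pattern = "^\\d+$")
  expect_error(merge_external_metadata(rec, unmapped), class = "prefixkit_consistency_error")
})

test_that("registry JSON round-trips losslessly and the schema document ships", {
  reg <- tiny_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry_json(reg, path)
  back <- read_registry_json(path)
  expect_identical(back$prefix, sort(reg$prefix))
  back <- back[match(reg$prefix, back$prefix), ]
  for (f in c("name", "homepage", "description", "pattern", "example", "uri_format",
              "preferred_prefix", "deprecated")) {
    expect_identical(back[[f]], reg[[f]], info = f)
  }
  expect_identical(back$synonyms, reg$synonyms)
  expect_identical(back$mappings, reg$mappings)
  expect_identical(back$providers, reg$providers)

  schema <- registry_json_schema()
  expect_true(all(c("name", "description") %in% unlist(schema$`$defs`$record$required)))
})
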