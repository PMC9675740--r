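test_that("build_lookup removes records already mapped to the registry being aligned", {
  reg <- tiny_registry() # alpha carries a mapping to "extreg"
  full <- build_lookup(reg, exclude_registry = "none-such")
  expect_setequal(unique(full$prefix), c("alpha", "beta", "gamma"))

  excl <- build_lookup(reg, exclude_registry = "extreg")
  expect_setequal(unique(excl$prefix), c("beta", "gamma"))

  expect_identical(nrow(build_lookup(empty_registry(), "extreg")), 0L)
  expect_error(build_lookup(collision_registry(), "extreg"),
               class = "prefixkit_collision_error")
})

test_that("align maps synonym and vocabulary variants onto curated records", {
  reg <- example_registry()
  dump <- dplyr::bind_rows(
    external_record("newreg", "FlyBase"),  # abbreviation record: synonym fb, prefix flybase
    external_record("newreg", "intenz"),   # vocabulary variant curated as synonym on eccode
    external_record("newreg", "randomont") # no lookup hit
  )
  res <- align(reg, group_meta("newreg", 2L), dump)
  expect_identical(res$new_mappings$prefix, c("flybase", "eccode"))
  expect_identical(res$new_mappings$external_prefix, c("FlyBase", "intenz"))
  expect_identical(res$new_mappings$provenance, c("automated", "automated"))
  expect_identical(res$curation_rows$external_prefix, "randomont")
  expect_identical(nrow(res$new_records), 0L) # group 2 never creates records
})

test_that("align dispatches unmatched prefixes by policy group and partitions the dump", {
  reg <- example_registry()
  dump <- dplyr::bind_rows(
    external_record("r", "GO"),                       # lookup hit
    external_record("r", "novelone", name = "Novel"), # miss
    external_record("r", "noveltwo")                  # miss
  )
  for (group in 1:3) {
    res <- align(reg, group_meta("r", group), dump)
    g <- glance(res)
    expect_identical(g$n_mapped + g$n_new_records + g$n_curation + g$n_skipped,
                     g$n_input)
    expect_identical(g$n_mapped, 1L)
    expect_identical(g$n_new_records, if (group == 1L) 2L else 0L)
    expect_identical(g$n_curation, if (group == 2L) 2L else 0L)
    expect_identical(g$n_skipped, if (group == 3L) 2L else 0L)
    if (group == 3L) {
      expect_setequal(res$skipped$reason, "group-3-unmatched")
    }
  }
  expect_error(align(reg, registry_meta("r"), dplyr::mutate(dump, registry_key = "other")),
               class = "prefixkit_config_error")
  bad_meta <- dplyr::mutate(registry_meta("r"), policy_group = 9L)
  expect_error(align(reg, bad_meta, dump), class = "prefixkit_config_error")
})

test_that("already-mapped external prefixes are skipped, and the blocklist suppresses hits", {
  reg <- example_registry() # ncbitaxon already mapped to (miriam, taxonomy)
  dump <- dplyr::bind_rows(
    external_record("miriam", "taxonomy"),
    external_record("miriam", "cars")
  )
  bl <- blocklist("miriam", "cars", "eccode")
  reg_cars <- dplyr::bind_rows(reg, new_record("cars", name = "x", homepage = "h",
                                               description = "d"))
  # blocklist consulted only on hits: block the true hit for "cars"
  res <- align(reg_cars, group_meta("miriam", 1L), dump,
               blocklist = blocklist("miriam", "cars", "cars"))
  expect_identical(sort(res$skipped$reason), c("already-mapped", "blocklisted"))
  expect_identical(nrow(res$new_mappings), 0L)
  # a blocklist entry for a different record does not suppress the mapping
  res2 <- align(reg_cars, group_meta("miriam", 1L), dump, blocklist = bl)
  expect_identical(res2$new_mappings$prefix, "cars")
})

test_that("group-1 misses synthesize records with deterministic, collision-safe prefixes", {
  reg <- example_registry()
  dump <- dplyr::bind_rows(
    external_record("r", "Novel-DB", name = "Novel DB", homepage = "https://novel.org",
                    pattern = "^\\d+$", example = "12", uri_format = "https://novel.org/$1"),
    external_record("r", "GONT") # normalizes onto go's synonym "gont": lookup hit
  )
  res <- align(reg, group_meta("r", 1L), dump)
  expect_identical(res$new_records$prefix, "noveldb")
  expect_identical(res$new_records$pattern, "^\\d+$")
  expect_identical(res$new_mappings$prefix, "go")

  # planted prefix collision: the synthesized record is now mapped to "r", so a
  # second spelling of the same name misses the lookup but finds its key taken
  # and is suffixed with the registry key
  reg2 <- apply_result(reg, res)
  dump2 <- external_record("r", "novel_db")
  res2 <- align(reg2, group_meta("r", 1L), dump2)
  expect_identical(res2$new_records$prefix, "noveldb.r")
})

test_that("apply_result merges all-or-nothing and re-running the dump is idempotent", {
  reg <- example_registry()
  dump <- dplyr::bind_rows(
    external_record("newreg", "FlyBase"),
    external_record("newreg", "intenz"),
    external_record("newreg", "brandnew", name = "Brand New", homepage = "https://bn.org")
  )
  meta <- group_meta("newreg", 1L)
  res <- align(reg, meta, dump)
  reg2 <- apply_result(reg, res)
  expect_identical(nrow(reg2), nrow(reg) + 1L)
  expect_identical(nrow(registry_mapping_table(reg2)),
                   nrow(registry_mapping_table(reg)) + 3L) # 2 hits + 1 on the new record

  # run-twice oracle: realigning the same dump yields no new mappings or records
  res_again <- align(reg2, meta, dump)
  expect_identical(nrow(res_again$new_mappings), 0L)
  expect_identical(nrow(res_again$new_records), 0L)
  expect_setequal(res_again$skipped$reason, "already-mapped")
  expect_identical(apply_result(reg2, res_again), reg2)

  # a stale result whose new record collides with an existing synonym aborts cleanly
  bad <- res
  bad$new_records <- new_record("fb", name = "imposter", homepage = "h", description = "d")
  expect_error(apply_result(reg, bad), class = "prefixkit_qa_error")
})

test_that("permuting dump rows leaves the mapping set unchanged", {
  truth <- generate_truth(40, synonyms_per_record = 2, seed = 11)
  ds <- derive_dump(truth, "r", perturb_profile(novel_rate = 0.1), seed = 5)
  meta <- group_meta("r", 1L)
  res_fwd <- align(truth$registry, meta, ds$dump)
  res_rev <- align(truth$registry, meta, ds$dump[rev(seq_len(nrow(ds$dump))), ])
  key <- function(m) sort(paste(m$prefix, m$registry_key, m$external_prefix))
  expect_identical(key(res_fwd$new_mappings), key(res_rev$new_mappings))
  expect_setequal(res_fwd$new_records$prefix, res_rev$new_records$prefix)
})

test_that("the curation sheet is written with the documented columns", {
  reg <- example_registry()
  dump <- external_record("r", "mystery", name = "Mystery", homepage = "https://m.org")
  res <- align(reg, group_meta("r", 2L), dump)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curation_sheet(res, path)
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  expect_identical(names(sheet),
                   c("registry_key", "external_prefix", "name", "homepage", "example", "uri_format"))
  expect_identical(sheet$external_prefix, "mystery")
})
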