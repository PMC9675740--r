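# Small hand-built fixtures used across the suite; everything is generated
# in code so the repository stays text-only.

tiny_registry <- function() {
  dplyr::bind_rows(
    new_record(
      "alpha",
      name = "Alpha Resource", homepage = "https://alpha.example.org",
      description = "First test resource.",
      preferred_prefix = "Alpha",
      synonyms = c("alpha-db", "adb"),
      pattern = "^\\d{4}$", example = "1234",
      uri_format = "https://alpha.example.org/id/$1",
      providers = provider("rsv", "Resolver", "https://resolver.example.org/alpha:$1", "resolver"),
      mappings = tibble::tibble(registry_key = "extreg", external_prefix = "ALPHA",
                                provenance = "curated")
    ),
    new_record(
      "beta",
      name = "Beta Resource", homepage = "https://beta.example.org",
      description = "Second test resource.",
      synonyms = c("bt"),
      pattern = "^B\\d+$", example = "B77",
      uri_format = "https://beta.example.org/entry/$1"
    ),
    new_record(
      "gamma",
      name = "Gamma Resource", homepage = "https://gamma.example.org",
      description = "Third test resource; no pattern curated.",
      uri_format = "https://gamma.example.org/$1/view"
    )
  )
}

# registry in which two records claim the same normalized synonym key
collision_registry <- function() {
  dplyr::bind_rows(
    new_record("taxone", name = "Taxonomy One", homepage = "https://one.example.org",
               description = "x", synonyms = c("taxon")),
    new_record("taxtwo", name = "Taxonomy Two", homepage = "https://two.example.org",
               description = "x", synonyms = c("TAX-ON"))
  )
}

group_meta <- function(key, group, order = 1L) {
  registry_meta(key, policy_group = group, import_order = order)
}
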