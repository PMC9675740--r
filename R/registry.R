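#' Registry records as tidy data
#'
#' A registry is a tibble with one row per identifier resource. Scalar
#' metadata live in character/logical columns; multi-valued metadata live in
#' list-columns:
#'
#' * `synonyms`, `depends_on` — character vectors;
#' * `providers` — a tibble with columns `code`, `name`, `uri_format`,
#'   `category` (one of first-party / third-party / resolver);
#' * `mappings` — a tibble with columns `registry_key`, `external_prefix`,
#'   `provenance`: the record's cross-registry equivalence mappings;
#' * `contributor`, `reviewer` — attribution lists (`name`, `orcid`).
#'
#' `new_record()` builds a one-row registry tibble; bind rows to grow a
#' registry. `empty_registry()` returns the zero-row prototype.
#'
#' @param prefix canonical prefix; must match `^[a-z0-9][a-z0-9._-]*$`.
#' @param name human-readable label.
#' @param homepage,description,license,version,contact optional scalar
#'   metadata (homepage and description are required for non-deprecated
#'   records at validation time).
#' @param preferred_prefix optional stylized prefix (e.g. `"GO"`).
#' @param synonyms character vector of prefix synonyms.
#' @param pattern regular expression for local unique identifiers; matched
#'   anchored (a full match) during validation.
#' @param example example local unique identifier.
#' @param uri_format primary URI format string containing exactly one `$1`
#'   placeholder.
#' @param providers tibble of providers (see above), or `NULL`.
#' @param deprecated,proprietary logical flags.
#' @param replaced_by canonical prefix of the replacing record (implies
#'   `deprecated`).
#' @param depends_on character vector of canonical prefixes this resource
#'   reuses terms from.
#' @param mappings tibble of cross-registry mappings (see above), or `NULL`.
#' @param contributor,reviewer attribution created with [attribution()], or
#'   `NULL`.
#' @param download_obo,download_owl,download_json optional artifact URLs
#'   (stored, never fetched).
#'
#' @return A one-row registry tibble.
#' @examples
#' r <- new_record("go",
#'   name = "Gene Ontology", homepage = "http://geneontology.org",
#'   description = "Ontology of gene functions.",
#'   preferred_prefix = "GO", pattern = "^\\d{7}$", example = "0006915",
#'   uri_format = "http://purl.obolibrary.org/obo/GO_$1"
#' )
#' validate_record(r)
#' @export
new_record <- function(prefix,
                       name = NA_character_,
                       homepage = NA_character_,
                       description = NA_character_,
                       preferred_prefix = NA_character_,
                       synonyms = character(),
                       pattern = NA_character_,
                       example = NA_character_,
                       uri_format = NA_character_,
                       providers = NULL,
                       deprecated = FALSE,
                       proprietary = FALSE,
                       replaced_by = NA_character_,
                       depends_on = character(),
                       mappings = NULL,
                       contributor = NULL,
                       reviewer = NULL,
                       download_obo = NA_character_,
                       download_owl = NA_character_,
                       download_json = NA_character_,
                       license = NA_character_,
                       version = NA_character_,
                       contact = NA_character_) {
  stopifnot(is.character(prefix), length(prefix) == 1L)
  tibble::tibble(
    prefix = prefix,
    preferred_prefix = as.character(preferred_prefix),
    name = as.character(name),
    homepage = as.character(homepage),
    description = as.character(description),
    synonyms = list(as.character(synonyms)),
    pattern = as.character(pattern),
    example = as.character(example),
    uri_format = as.character(uri_format),
    providers = list(as_providers(providers)),
    deprecated = isTRUE(deprecated),
    proprietary = isTRUE(proprietary),
    replaced_by = as.character(replaced_by),
    depends_on = list(as.character(depends_on)),
    mappings = list(as_mappings(mappings)),
    contributor = list(contributor),
    reviewer = list(reviewer),
    download_obo = as.character(download_obo),
    download_owl = as.character(download_owl),
    download_json = as.character(download_json),
    license = as.character(license),
    version = as.character(version),
    contact = as.character(contact)
  )
}

#' @rdname new_record
#' @export
empty_registry <- function() {
  new_record("x")[0, ]
}

#' Build a provider entry
#'
#' @param code short provider identifier, unique within a record.
#' @param name human-readable provider name.
#' @param uri_format URI format string with exactly one `$1` placeholder.
#' @param category one of `"first-party"`, `"third-party"`, `"resolver"`.
#' @return A one-row provider tibble.
#' @export
provider <- function(code, name, uri_format,
                     category = c("first-party", "third-party", "resolver")) {
  category <- match.arg(category)
  tibble::tibble(
    code = as.character(code), name = as.character(name),
    uri_format = as.character(uri_format), category = category
  )
}

empty_providers <- function() provider("x", "x", "x")[0, ]

as_providers <- function(x) {
  if (is.null(x)) return(empty_providers())
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  stopifnot(all(c("code", "name", "uri_format", "category") %in% names(x)))
  x[, c("code", "name", "uri_format", "category")]
}

empty_mappings <- function() {
  tibble::tibble(
    registry_key = character(), external_prefix = character(),
    provenance = character()
  )
}

as_mappings <- function(x) {
  if (is.null(x)) return(empty_mappings())
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!"provenance" %in% names(x)) x$provenance <- "curated"
  stopifnot(all(c("registry_key", "external_prefix") %in% names(x)))
  x[, c("registry_key", "external_prefix", "provenance")]
}

#' Attribution of a record to a person
#'
#' @param name contributor or reviewer name.
#' @param orcid ORCID identifier (`dddd-dddd-dddd-dddX`).
#' @return A named list usable in `contributor`/`reviewer` fields.
#' @export
attribution <- function(name, orcid = NA_character_) {
  list(name = as.character(name), orcid = as.character(orcid))
}

#' Group prefixes into a named collection
#'
#' Collections contextualize subsets of the registry (e.g. prefixes useful
#' on the Semantic Web). Members must exist in the registry; checked by
#' [validate_registry()].
#'
#' @param id collection identifier.
#' @param name,description collection metadata.
#' @param members character vector of canonical prefixes.
#' @return A one-row collection tibble with a `members` list-column.
#' @export
collection <- function(id, name, description = NA_character_, members = character()) {
  tibble::tibble(
    id = as.character(id), name = as.character(name),
    description = as.character(description), members = list(as.character(members))
  )
}

PREFIX_RE <- "^[a-z0-9][a-z0-9._-]*$"
ORCID_RE <- "^[0-9]{4}-[0-9]{4}-[0-9]{4}-[0-9]{3}[0-9X]$"
PLACEHOLDER <- "$1"

count_placeholders <- function(fmt) {
  if (is.na(fmt)) return(NA_integer_)
  m <- gregexpr(PLACEHOLDER, fmt, fixed = TRUE)[[1]]
  if (identical(as.integer(m), -1L)) 0L else length(m)
}

strip_outer_anchors <- function(pattern) {
  if (startsWith(pattern, "^")) pattern <- substring(pattern, 2L)
  n <- nchar(pattern)
  if (n > 0L && substring(pattern, n, n) == "$") {
    # only strip a terminal "$" that is a true anchor, not an escaped "\\$"
    bs <- 0L
    i <- n - 1L
    while (i >= 1L && substring(pattern, i, i) == "\\") {
      bs <- bs + 1L
      i <- i - 1L
    }
    if (bs %% 2L == 0L) pattern <- substring(pattern, 1L, n - 1L)
  }
  pattern
}

#' Anchored (full-string) pattern matching for local unique identifiers
#'
#' Identifier patterns are matched against the whole identifier: patterns
#' stored without surrounding anchors are implicitly anchored, so a prefixed
#' form such as `"GO:0006915"` fails a `^\d{7}$`-style pattern.
#'
#' @param pattern regular expression source.
#' @param x character vector of candidate identifiers.
#' @return Logical vector.
#' @export
matches_pattern <- function(pattern, x) {
  re <- paste0("^(?:", strip_outer_anchors(pattern), ")$")
  ok <- tryCatch(grepl(re, x, perl = TRUE), error = function(e) rep(NA, length(x)))
  ok
}

violation <- function(prefix, check, field, message) {
  tibble::tibble(
    prefix = prefix, check = check, field = field, message = message
  )
}

no_violations <- function() violation(character(), character(), character(), character())

is_blank <- function(x) is.na(x) | !nzchar(x)

#' Validate a single registry record
#'
#' Checks every record-level invariant and returns the violations as data
#' (one row per broken invariant) rather than raising: a malformed record is
#' a curation problem, not an exception.
#'
#' Checked invariants: canonical prefix shape; prefix not among its own
#' synonyms and synonyms pairwise distinct after [norm_key()]; `example`
#' fully matches `pattern` when both are present; `uri_format` (record and
#' providers) contains exactly one `$1` placeholder; `replaced_by` implies
#' `deprecated`; required metadata present (`name`, `homepage`,
#' `description`; deprecated records only need `name` and `description`);
#' ORCID shape for attributions.
#'
#' @param record a one-row (or multi-row) registry tibble; multi-row input
#'   is validated row-wise.
#' @return A tibble of violations with columns `prefix`, `check`, `field`,
#'   `message`; zero rows iff the record is valid.
#' @export
validate_record <- function(record) {
  stopifnot(is.data.frame(record))
  if (nrow(record) == 0L) return(no_violations())
  purrr::map_dfr(seq_len(nrow(record)), function(i) validate_record_one(record[i, ]))
}

validate_record_one <- function(r) {
  p <- r$prefix
  out <- list()
  add <- function(check, field, message) {
    out[[length(out) + 1L]] <<- violation(p, check, field, message)
  }

  if (is.na(p) || !grepl(PREFIX_RE, p)) {
    add("prefix-shape", "prefix",
        sprintf("prefix %s is not a lowercase canonical prefix", encodeString(p, quote = "\"")))
  }

  syn <- r$synonyms[[1]]
  if (!is.na(p) && p %in% syn) {
    add("prefix-in-synonyms", "synonyms", sprintf("prefix '%s' listed among its own synonyms", p))
  }
  if (length(syn) > 1L) {
    keys <- norm_key(syn)
    if (anyDuplicated(keys)) {
      dup <- syn[duplicated(keys) | duplicated(keys, fromLast = TRUE)]
      add("synonym-collision", "synonyms",
          sprintf("synonyms not distinct after key normalization: %s",
                  paste(unique(dup), collapse = ", ")))
    }
  }

  if (!is.na(r$pattern) && !is.na(r$example)) {
    ok <- matches_pattern(r$pattern, r$example)
    if (is.na(ok)) {
      add("pattern-invalid", "pattern", sprintf("pattern '%s' is not a valid regular expression", r$pattern))
    } else if (!ok) {
      add("pattern-mismatch", "example",
          sprintf("example '%s' does not fully match pattern '%s'", r$example, r$pattern))
    }
  }

  if (!is.na(r$uri_format)) {
    k <- count_placeholders(r$uri_format)
    if (k != 1L) {
      add("placeholder", "uri_format",
          sprintf("uri_format '%s' has %d '$1' placeholders; exactly one required", r$uri_format, k))
    }
  }
  prov <- r$providers[[1]]
  if (nrow(prov)) {
    bad <- vapply(prov$uri_format, count_placeholders, integer(1)) != 1L
    if (any(bad)) {
      add("placeholder", "providers",
          sprintf("provider(s) %s lack exactly one '$1' placeholder",
                  paste(prov$code[bad], collapse = ", ")))
    }
    if (anyDuplicated(prov$code)) {
      add("provider-code", "providers", "provider codes not unique within record")
    }
  }

  if (!is.na(r$replaced_by) && !isTRUE(r$deprecated)) {
    add("replaced-not-deprecated", "replaced_by",
        sprintf("replaced_by is set ('%s') but record is not deprecated", r$replaced_by))
  }

  required <- if (isTRUE(r$deprecated)) c("name", "description") else c("name", "homepage", "description")
  for (f in required) {
    if (is_blank(r[[f]])) add("required-field", f, sprintf("required field '%s' is missing", f))
  }

  map <- r$mappings[[1]]
  if (nrow(map) && anyDuplicated(map$registry_key)) {
    add("mapping-multiplicity", "mappings",
        "more than one external prefix mapped for a single registry")
  }

  for (f in c("contributor", "reviewer")) {
    a <- r[[f]][[1]]
    if (!is.null(a) && !is.na(a$orcid %||% NA_character_) && !grepl(ORCID_RE, a$orcid)) {
      add("orcid-shape", f, sprintf("ORCID '%s' does not match the standard pattern", a$orcid))
    }
  }

  if (length(out)) dplyr::bind_rows(out) else no_violations()
}

#' Validate a whole registry, including global invariants
#'
#' Runs [validate_record()] over all records, then checks the registry-wide
#' invariants: the multiset of key-normalized prefixes, preferred prefixes,
#' and synonyms has no duplicates across records (the collision-free lookup
#' guarantee underlying [build_prefix_index()]); each (registry_key,
#' external_prefix) pair appears in at most one record's mappings;
#' `replaced_by` and `depends_on` targets and collection members exist.
#'
#' @param registry a registry tibble.
#' @param collections optional collection tibble (see [collection()]).
#' @return A violations tibble as in [validate_record()]; zero rows iff the
#'   registry passes QA.
#' @export
validate_registry <- function(registry, collections = NULL) {
  out <- validate_record(registry)

  if (nrow(registry)) {
    if (anyDuplicated(registry$prefix)) {
      dup <- unique(registry$prefix[duplicated(registry$prefix)])
      out <- dplyr::bind_rows(out, violation(dup, "duplicate-prefix", "prefix",
                                             sprintf("prefix '%s' appears in more than one record", dup)))
    }
    keys <- registry_key_table(registry)
    coll <- keys |>
      dplyr::distinct(.data$key, .data$prefix) |>
      dplyr::group_by(.data$key) |>
      dplyr::filter(dplyr::n() > 1L) |>
      dplyr::ungroup()
    if (nrow(coll)) {
      out <- dplyr::bind_rows(out, coll |>
        dplyr::group_by(.data$key) |>
        dplyr::summarise(prefixes = paste(sort(.data$prefix), collapse = ", "), .groups = "drop") |>
        purrr::pmap_dfr(function(key, prefixes) {
          violation(prefixes, "lookup-collision", "synonyms",
                    sprintf("normalized key '%s' claimed by records: %s", key, prefixes))
        }))
    }

    allmap <- registry_mapping_table(registry)
    if (nrow(allmap)) {
      dup <- allmap |>
        dplyr::group_by(.data$registry_key, .data$external_prefix) |>
        dplyr::filter(dplyr::n() > 1L) |>
        dplyr::ungroup()
      if (nrow(dup)) {
        out <- dplyr::bind_rows(out, dup |>
          dplyr::distinct(.data$registry_key, .data$external_prefix) |>
          purrr::pmap_dfr(function(registry_key, external_prefix) {
            violation(NA_character_, "mapping-collision", "mappings",
                      sprintf("external prefix '%s' in registry '%s' mapped by multiple records",
                              external_prefix, registry_key))
          }))
      }
    }

    for (f in c("replaced_by")) {
      tgt <- registry[[f]]
      bad <- !is.na(tgt) & !(tgt %in% registry$prefix)
      if (any(bad)) {
        out <- dplyr::bind_rows(out, violation(registry$prefix[bad], "dangling-reference", f,
                                               sprintf("%s target '%s' not in registry", f, tgt[bad])))
      }
    }
    dep <- tidyr::unnest(registry[, c("prefix", "depends_on")], "depends_on")
    if (nrow(dep)) {
      bad <- !(dep$depends_on %in% registry$prefix)
      if (any(bad)) {
        out <- dplyr::bind_rows(out, violation(dep$prefix[bad], "dangling-reference", "depends_on",
                                               sprintf("depends_on target '%s' not in registry", dep$depends_on[bad])))
      }
    }
  }

  if (!is.null(collections) && nrow(collections)) {
    mem <- tidyr::unnest(collections[, c("id", "members")], "members")
    bad <- !(mem$members %in% registry$prefix)
    if (any(bad)) {
      out <- dplyr::bind_rows(out, violation(mem$members[bad], "collection-member", "members",
                                             sprintf("collection '%s' member '%s' not in registry",
                                                     mem$id[bad], mem$members[bad])))
    }
  }

  out
}

# one row per (normalized key, record): canonical + preferred + synonyms
registry_key_table <- function(registry) {
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    raw <- unique(c(r$prefix, if (!is.na(r$preferred_prefix)) r$preferred_prefix, r$synonyms[[1]]))
    raw <- raw[!is.na(raw) & nzchar(raw)]
    tibble::tibble(key = norm_key(raw), prefix = r$prefix, source = raw)
  }) |>
    dplyr::distinct(.data$key, .data$prefix, .keep_all = TRUE)
}

#' All cross-registry mappings of a registry as one tidy table
#'
#' @param registry a registry tibble.
#' @return A tibble with columns `prefix`, `registry_key`,
#'   `external_prefix`, `provenance`; one row per mapping (the
#'   metaregistry edge list).
#' @export
registry_mapping_table <- function(registry) {
  if (!nrow(registry)) {
    return(tibble::tibble(prefix = character(), registry_key = character(),
                          external_prefix = character(), provenance = character()))
  }
  tidyr::unnest(registry[, c("prefix", "mappings")], "mappings")
}

#' Merge metadata imported from an external registry into a curated record
#'
#' Imported metadata never overwrites curation: only fields that are empty
#' on the record (`name`, `homepage`, `description`, `example`, `pattern`,
#' `uri_format`) are filled from the external record. Idempotent.
#'
#' @param record a one-row registry tibble.
#' @param ext a one-row external-record tibble (see [external_record()]);
#'   its `registry_key`/`external_prefix` must match one of the record's
#'   mappings, otherwise a consistency error is raised.
#' @return The merged one-row registry tibble.
#' @export
merge_external_metadata <- function(record, ext) {
  stopifnot(is.data.frame(record), nrow(record) == 1L,
            is.data.frame(ext), nrow(ext) == 1L)
  map <- record$mappings[[1]]
  hit <- map$registry_key == ext$registry_key & map$external_prefix == ext$external_prefix
  if (!any(hit)) {
    rlang::abort(sprintf(
      "external record (%s, %s) does not match any mapping on record '%s'",
      ext$registry_key, ext$external_prefix, record$prefix
    ), class = "prefixkit_consistency_error")
  }
  for (f in c("name", "homepage", "description", "example", "pattern", "uri_format")) {
    if (f %in% names(ext) && is_blank(record[[f]]) && !is_blank(ext[[f]])) {
      record[[f]] <- ext[[f]]
    }
  }
  record
}

#' A normalized row from an external registry dump
#'
#' External registries are heterogeneous; after download and normalization
#' exactly one field is annotated as the external prefix, and whatever other
#' metadata the registry supplies rides along (optional).
#'
#' @param registry_key key of the external registry (see [registry_meta()]).
#' @param external_prefix the prefix string used by that registry; non-empty.
#' @param name,homepage,example,pattern,uri_format optional metadata.
#' @return A one-row external-record tibble.
#' @export
external_record <- function(registry_key, external_prefix,
                            name = NA_character_, homepage = NA_character_,
                            example = NA_character_, pattern = NA_character_,
                            uri_format = NA_character_) {
  stopifnot(nzchar(external_prefix))
  tibble::tibble(
    registry_key = as.character(registry_key),
    external_prefix = as.character(external_prefix),
    name = as.character(name), homepage = as.character(homepage),
    example = as.character(example), pattern = as.character(pattern),
    uri_format = as.character(uri_format)
  )
}

#' Describe an external registry (the metaregistry side)
#'
#' Capability flags record which metadata fields the external registry's
#' schema supplies; the policy group controls how unmatched prefixes are
#' handled during alignment: group 1 registries (well-curated, biomedical,
#' prefix-focused) contribute new records; group 2 registries are queued on
#' a curation sheet; group 3 registries (minimal metadata or out of scope)
#' are skipped silently.
#'
#' @param key registry short name, e.g. `"obofoundry"`.
#' @param name,homepage registry metadata.
#' @param policy_group 1, 2, or 3 (import policy; editorial configuration,
#'   not inferred).
#' @param import_order integer rank; registries are aligned sequentially in
#'   this order and earlier registries win naming conflicts.
#' @param has_name,has_homepage,has_description,has_example,has_pattern,has_provider,has_license,has_version
#'   capability flags.
#' @return A one-row registry-meta tibble.
#' @export
registry_meta <- function(key, name = key, homepage = NA_character_,
                          policy_group = 1L, import_order = 1L,
                          has_name = TRUE, has_homepage = FALSE,
                          has_description = FALSE, has_example = FALSE,
                          has_pattern = FALSE, has_provider = FALSE,
                          has_license = FALSE, has_version = FALSE) {
  if (!policy_group %in% 1:3) {
    rlang::abort(sprintf("policy_group must be 1, 2, or 3 (got %s)", policy_group),
                 class = "prefixkit_config_error")
  }
  tibble::tibble(
    key = as.character(key), name = as.character(name),
    homepage = as.character(homepage),
    policy_group = as.integer(policy_group),
    import_order = as.integer(import_order),
    has_name = has_name, has_homepage = has_homepage,
    has_description = has_description, has_example = has_example,
    has_pattern = has_pattern, has_provider = has_provider,
    has_license = has_license, has_version = has_version
  )
}
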