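#' Export a prefix-map context
#'
#' A context maps prefixes (e.g. `chebi`) to URI prefixes (e.g.
#' `http://purl.obolibrary.org/obo/CHEBI_`). Only records whose URI format
#' *ends* in the placeholder are eligible (the URI prefix is the format with
#' the trailing `$1` removed); deprecated records and non-terminal formats
#' are excluded (the latter with a warning). Deterministic: entries are
#' sorted by canonical prefix.
#'
#' Profiles select the casing policy: `full` and `semweb` emit canonical
#' lowercase prefixes; `obo` emits the preferred (stylized) prefix where one
#' is curated. Membership can be narrowed to a collection's prefixes.
#'
#' URI-prefix duplicates are resolved by keeping the first entry in prefix
#' order with a warning, or raised as an error listing the colliding
#' prefixes when `strict = TRUE`.
#'
#' @param registry a registry tibble.
#' @param profile one of `"full"`, `"obo"`, `"semweb"`.
#' @param collection optional character vector of canonical prefixes (e.g.
#'   a [collection()]'s `members`) restricting membership.
#' @param strict error (rather than drop) on URI-prefix collision.
#' @return A tibble of class `prefix_map` with columns `prefix`,
#'   `uri_prefix`.
#' @export
export_context <- function(registry, profile = c("full", "obo", "semweb"),
                           collection = NULL, strict = FALSE) {
  profile <- match.arg(profile)
  reg <- registry[!registry$deprecated, , drop = FALSE]
  if (!is.null(collection)) reg <- reg[reg$prefix %in% collection, , drop = FALSE]
  reg <- reg[!is.na(reg$uri_format), , drop = FALSE]
  ok1 <- vapply(reg$uri_format, count_placeholders, integer(1)) == 1L
  terminal <- endsWith(reg$uri_format, PLACEHOLDER)
  if (any(ok1 & !terminal)) {
    rlang::warn(sprintf(
      "excluded from context (placeholder not terminal): %s",
      paste(reg$prefix[ok1 & !terminal], collapse = ", ")
    ))
  }
  reg <- reg[ok1 & terminal, , drop = FALSE]
  shown <- if (profile == "obo") {
    ifelse(is.na(reg$preferred_prefix), reg$prefix, reg$preferred_prefix)
  } else {
    reg$prefix
  }
  out <- tibble::tibble(
    prefix = shown,
    uri_prefix = substring(reg$uri_format, 1L, nchar(reg$uri_format) - nchar(PLACEHOLDER))
  )
  out <- out[order(out$prefix), , drop = FALSE]
  if (anyDuplicated(out$uri_prefix)) {
    dup_vals <- unique(out$uri_prefix[duplicated(out$uri_prefix)])
    clash <- out$prefix[out$uri_prefix %in% dup_vals]
    if (strict) {
      rlang::abort(sprintf("URI prefix collision in context: %s", paste(clash, collapse = ", ")),
                   class = "prefixkit_collision_error")
    }
    rlang::warn(sprintf("URI prefix collision; dropped later entries: %s",
                        paste(clash[duplicated(out$uri_prefix)], collapse = ", ")))
    out <- out[!duplicated(out$uri_prefix), , drop = FALSE]
  }
  class(out) <- c("prefix_map", class(out))
  out
}

#' Write a prefix map as a JSON-LD context document
#'
#' @param prefix_map an [export_context()] result.
#' @param path output path; the document is `{"@context": {prefix: uri
#'   prefix, ...}}` with sorted keys.
#' @return `path`, invisibly.
#' @export
write_context <- function(prefix_map, path) {
  ctx <- as.list(stats::setNames(prefix_map$uri_prefix, prefix_map$prefix))
  ctx <- ctx[order(names(ctx))]
  jsonlite::write_json(list(`@context` = ctx), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

SSSOM_PREDICATE <- "skos:exactMatch"
SSSOM_JUSTIFICATION <- "semapv:ManualMappingCuration"

#' Export the metaregistry as an SSSOM mapping set
#'
#' One row per cross-registry mapping: the subject is the record's CURIE in
#' the registry's own namespace, the object is the registry-scoped CURIE of
#' the external prefix, and the predicate is a fixed exact-match term.
#'
#' @param registry a registry tibble.
#' @param subject_namespace CURIE prefix used for subjects.
#' @param license,mapping_date header metadata.
#' @return An object of class `sssom_doc`: list with `metadata` (named
#'   list) and `rows` (tibble `subject_id`, `predicate_id`, `object_id`,
#'   `mapping_justification`).
#' @export
export_sssom <- function(registry, subject_namespace = "bioregistry",
                         license = "https://creativecommons.org/publicdomain/zero/1.0/",
                         mapping_date = "1970-01-01") {
  m <- registry_mapping_table(registry)
  rows <- tibble::tibble(
    subject_id = paste0(subject_namespace, ":", m$prefix),
    predicate_id = rep(SSSOM_PREDICATE, nrow(m)),
    object_id = paste0(m$registry_key, ":", m$external_prefix),
    mapping_justification = rep(SSSOM_JUSTIFICATION, nrow(m))
  )
  rows <- rows[order(rows$subject_id, rows$object_id), , drop = FALSE]
  structure(
    list(
      metadata = list(
        mapping_set_id = paste0("https://example.org/", subject_namespace, "/mappings.sssom.tsv"),
        license = license,
        mapping_date = as.character(mapping_date)
      ),
      rows = rows
    ),
    class = "sssom_doc"
  )
}

#' Write an SSSOM document as TSV with an embedded YAML header
#'
#' The header metadata is serialized as YAML, each line prefixed with
#' `"# "`, followed by the tab-separated mapping table.
#'
#' @param doc an [export_sssom()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sssom <- function(doc, path) {
  stopifnot(inherits(doc, "sssom_doc"))
  header <- strsplit(yaml::as.yaml(doc$metadata), "\n", fixed = TRUE)[[1]]
  con <- file(path, open = "wb") # binary mode keeps LF endings everywhere
  on.exit(close(con))
  writeLines(paste0("# ", header), con, sep = "\n")
  writeLines(paste(names(doc$rows), collapse = "\t"), con, sep = "\n")
  if (nrow(doc$rows)) {
    writeLines(do.call(paste, c(as.list(doc$rows), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read back an SSSOM TSV written by [write_sssom()]
#'
#' @param path input path.
#' @return An `sssom_doc`.
#' @export
read_sssom <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "# ")
  metadata <- yaml::yaml.load(paste(sub("^# ", "", lines[is_meta]), collapse = "\n"))
  body <- lines[!is_meta]
  rows <- readr::read_tsv(I(paste(body, collapse = "\n")), col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  structure(list(metadata = metadata, rows = tibble::as_tibble(rows)), class = "sssom_doc")
}

#' @export
print.sssom_doc <- function(x, ...) {
  cat(sprintf("<sssom_doc> %d mapping(s), license %s\n", nrow(x$rows), x$metadata$license))
  invisible(x)
}

#' @method tidy sssom_doc
#' @export
tidy.sssom_doc <- function(x, ...) x$rows

#' @method glance sssom_doc
#' @export
glance.sssom_doc <- function(x, ...) {
  tibble::tibble(n_mappings = nrow(x$rows),
                 n_registries = length(unique(sub(":.*$", "", x$rows$object_id))),
                 license = x$metadata$license)
}

TSV_LIST_SEP <- "|"
TSV_COLUMNS <- c(
  "prefix", "preferred_prefix", "name", "homepage", "description",
  "synonyms", "pattern", "example", "uri_format", "deprecated",
  "proprietary", "replaced_by", "depends_on", "mappings",
  "download_obo", "download_owl", "download_json", "license", "version",
  "contact"
)

#' Flatten the registry to a fixed-column TSV table
#'
#' One row per record, fixed column order; list fields are joined with
#' `"|"` and mappings rendered as `registry_key:external_prefix` pairs.
#' Providers and attribution stay in the JSON source of truth and are not
#' carried in the TSV.
#'
#' @param registry a registry tibble.
#' @return A flat tibble with the columns in `TSV_COLUMNS` order.
#' @export
export_tsv <- function(registry) {
  join <- function(x) vapply(x, function(v) paste(v, collapse = TSV_LIST_SEP), character(1))
  tibble::tibble(
    prefix = registry$prefix,
    preferred_prefix = registry$preferred_prefix,
    name = registry$name,
    homepage = registry$homepage,
    description = registry$description,
    synonyms = join(registry$synonyms),
    pattern = registry$pattern,
    example = registry$example,
    uri_format = registry$uri_format,
    deprecated = registry$deprecated,
    proprietary = registry$proprietary,
    replaced_by = registry$replaced_by,
    depends_on = join(registry$depends_on),
    mappings = vapply(registry$mappings, function(m) {
      paste(paste0(m$registry_key, ":", m$external_prefix), collapse = TSV_LIST_SEP)
    }, character(1)),
    download_obo = registry$download_obo,
    download_owl = registry$download_owl,
    download_json = registry$download_json,
    license = registry$license,
    version = registry$version,
    contact = registry$contact
  )[, TSV_COLUMNS]
}

#' @rdname export_tsv
#' @param path output path (UTF-8, LF line endings).
#' @export
write_registry_tsv <- function(registry, path) {
  readr::write_tsv(export_tsv(registry), path, na = "")
  invisible(path)
}

#' Read a registry TSV back into a registry tibble
#'
#' Inverse of [write_registry_tsv()] for all scalar fields plus the joined
#' list fields; providers and attribution are restored empty.
#'
#' @param path input path.
#' @return A registry tibble.
#' @export
read_registry_tsv <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    deprecated = "l", proprietary = "l", .default = "c"
  ), na = "", progress = FALSE)
  unjoin <- function(x) {
    lapply(x, function(v) if (is.na(v) || !nzchar(v)) character() else
      strsplit(v, TSV_LIST_SEP, fixed = TRUE)[[1]])
  }
  recs <- lapply(seq_len(nrow(flat)), function(i) {
    f <- flat[i, ]
    maps <- unjoin(f$mappings)[[1]]
    new_record(
      prefix = f$prefix, preferred_prefix = f$preferred_prefix,
      name = f$name, homepage = f$homepage, description = f$description,
      synonyms = unjoin(f$synonyms)[[1]],
      pattern = f$pattern, example = f$example, uri_format = f$uri_format,
      deprecated = isTRUE(f$deprecated), proprietary = isTRUE(f$proprietary),
      replaced_by = f$replaced_by, depends_on = unjoin(f$depends_on)[[1]],
      mappings = if (length(maps)) {
        tibble::tibble(
          registry_key = sub(":.*$", "", maps),
          external_prefix = sub("^[^:]*:", "", maps),
          provenance = "curated"
        )
      } else NULL,
      download_obo = f$download_obo, download_owl = f$download_owl,
      download_json = f$download_json, license = f$license,
      version = f$version, contact = f$contact
    )
  })
  if (length(recs)) dplyr::bind_rows(recs) else empty_registry()
}
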