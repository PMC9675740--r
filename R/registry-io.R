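#' Read and write the canonical registry JSON
#'
#' The single source of truth is one JSON object mapping each canonical
#' prefix to its record, UTF-8 encoded with sorted keys; empty fields are
#' omitted. `write_registry_json()` / `read_registry_json()` round-trip a
#' registry tibble losslessly. A JSON Schema for third-party validation of
#' this format ships with the package (see [registry_json_schema()]).
#'
#' @param registry a registry tibble.
#' @param path file path.
#' @return `write_registry_json()` returns `path` invisibly;
#'   `read_registry_json()` returns a registry tibble.
#' @export
write_registry_json <- function(registry, path) {
  recs <- lapply(seq_len(nrow(registry)), function(i) record_to_list(registry[i, ]))
  names(recs) <- registry$prefix
  recs <- recs[order(names(recs))]
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

record_to_list <- function(r) {
  out <- list()
  put <- function(field, value) {
    if (length(value) && !(length(value) == 1L && is.na(value))) out[[field]] <<- value
  }
  for (f in c("preferred_prefix", "name", "homepage", "description", "pattern",
              "example", "uri_format", "replaced_by", "download_obo",
              "download_owl", "download_json", "license", "version", "contact")) {
    put(f, r[[f]])
  }
  if (length(r$synonyms[[1]])) out$synonyms <- as.list(r$synonyms[[1]])
  if (length(r$depends_on[[1]])) out$depends_on <- as.list(r$depends_on[[1]])
  if (isTRUE(r$deprecated)) out$deprecated <- TRUE
  if (isTRUE(r$proprietary)) out$proprietary <- TRUE
  prov <- r$providers[[1]]
  if (nrow(prov)) {
    out$providers <- lapply(seq_len(nrow(prov)), function(j) as.list(prov[j, ]))
  }
  m <- r$mappings[[1]]
  if (nrow(m)) {
    out$mappings <- lapply(seq_len(nrow(m)), function(j) as.list(m[j, ]))
  }
  for (f in c("contributor", "reviewer")) {
    a <- r[[f]][[1]]
    if (!is.null(a)) out[[f]] <- a[!vapply(a, function(v) length(v) == 1L && is.na(v), logical(1))]
  }
  out
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  recs <- jsonlite::read_json(path)
  if (!length(recs)) return(empty_registry())
  rows <- lapply(names(recs), function(p) {
    x <- recs[[p]]
    g <- function(f) x[[f]] %||% NA_character_
    new_record(
      prefix = p,
      preferred_prefix = g("preferred_prefix"), name = g("name"),
      homepage = g("homepage"), description = g("description"),
      synonyms = unlist(x$synonyms) %||% character(),
      pattern = g("pattern"), example = g("example"), uri_format = g("uri_format"),
      providers = if (length(x$providers)) dplyr::bind_rows(lapply(x$providers, tibble::as_tibble)) else NULL,
      deprecated = isTRUE(x$deprecated), proprietary = isTRUE(x$proprietary),
      replaced_by = g("replaced_by"),
      depends_on = unlist(x$depends_on) %||% character(),
      mappings = if (length(x$mappings)) dplyr::bind_rows(lapply(x$mappings, tibble::as_tibble)) else NULL,
      contributor = x$contributor, reviewer = x$reviewer,
      download_obo = g("download_obo"), download_owl = g("download_owl"),
      download_json = g("download_json"), license = g("license"),
      version = g("version"), contact = g("contact")
    )
  })
  dplyr::bind_rows(rows)
}

#' The JSON Schema describing one registry record
#'
#' @return The parsed schema as a list; the raw document is installed at
#'   `system.file("schema", "registry-schema.json", package = "prefixkit")`.
#' @export
registry_json_schema <- function() {
  jsonlite::read_json(system.file("schema", "registry-schema.json", package = "prefixkit"))
}

#' Read a dump of external-registry records from TSV
#'
#' Columns: `registry_key`, `external_prefix`, and optionally `name`,
#' `homepage`, `example`, `pattern`, `uri_format`.
#'
#' @param path input TSV path.
#' @return A tibble of external records.
#' @export
read_dump_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"), na = "", progress = FALSE)
}

#' @rdname read_dump_tsv
#' @param dump a tibble of external records.
#' @export
write_dump_tsv <- function(dump, path) {
  readr::write_tsv(dump, path, na = "")
  invisible(path)
}
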