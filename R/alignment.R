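#' Build the alignment lookup table for one external registry
#'
#' The lookup covers the canonical prefix, preferred prefix, and all
#' synonyms of every record — except records that already carry a mapping
#' to the registry being aligned, which are removed so the run cannot remap
#' them. Collisions abort construction, naming both offending records.
#'
#' @param registry a registry tibble that passes [validate_registry()].
#' @param exclude_registry external registry key being aligned.
#' @return A `prefix_index` (see [build_prefix_index()]).
#' @export
build_lookup <- function(registry, exclude_registry) {
  build_prefix_index(registry, exclude_registry = exclude_registry)
}

#' A curated blocklist of known-incorrect candidate mappings
#'
#' Consulted only on lookup hits: a blocklisted triple suppresses the
#' automated mapping (it never creates one).
#'
#' @param registry_key,external_prefix,prefix character vectors (recycled)
#'   naming the suppressed (registry, external prefix, record) triples.
#' @return A blocklist tibble.
#' @export
blocklist <- function(registry_key = character(), external_prefix = character(),
                      prefix = character()) {
  tibble::tibble(
    registry_key = as.character(registry_key),
    external_prefix = as.character(external_prefix),
    prefix = as.character(prefix)
  )
}

#' Align an external registry dump against the registry
#'
#' Implements the sequential import workflow. For each dump row, in order:
#'
#' 1. if its external prefix is already mapped for this registry, it is
#'    skipped (`already-mapped`);
#' 2. otherwise its [norm_key()] is looked up in [build_lookup()];
#' 3. a hit that is not blocklisted (and whose record was not already
#'    consumed earlier in this run) becomes an automated
#'    cross-registry mapping;
#' 4. a miss is handled by the registry's policy group: group 1 synthesizes
#'    a new registry record from the row's metadata; group 2 emits a
#'    curation row for later manual review; group 3 is skipped silently
#'    (`group-3-unmatched`).
#'
#' The four outcome lists partition the dump exactly.
#'
#' @param registry a registry tibble passing QA.
#' @param meta a one-row [registry_meta()] tibble for the dump's registry.
#' @param dump a tibble of external records (see [external_record()]); all
#'   rows must carry `meta$key`.
#' @param blocklist optional [blocklist()] tibble.
#' @return An object of class `alignment_result`: a list with tibbles
#'   `new_mappings` (`prefix`, `registry_key`, `external_prefix`,
#'   `provenance = "automated"`), `new_records` (a registry tibble),
#'   `curation_rows` (external records), `skipped` (external records plus
#'   `reason`), and the scalar bookkeeping fields `registry_key`,
#'   `policy_group`, `n_input`.
#' @seealso [apply_result()], [score_alignment()], [tidy.alignment_result()]
#' @export
align <- function(registry, meta, dump, blocklist = NULL) {
  stopifnot(is.data.frame(meta), nrow(meta) == 1L, is.data.frame(dump))
  group <- meta$policy_group
  if (!isTRUE(group %in% 1:3)) {
    rlang::abort(sprintf("unknown policy group: %s", group),
                 class = "prefixkit_config_error")
  }
  if (nrow(dump) && !all(dump$registry_key == meta$key)) {
    rlang::abort("dump rows do not all carry the registry key being aligned",
                 class = "prefixkit_config_error")
  }

  lookup <- build_lookup(registry, exclude_registry = meta$key)
  existing <- registry_mapping_table(registry)
  already <- existing$external_prefix[existing$registry_key == meta$key]
  bl <- blocklist %||% blocklist()

  taken_keys <- if (nrow(registry)) registry_key_table(registry)$key else character()

  mappings <- list()
  new_records <- list()
  curation <- list()
  skipped <- list()
  used_prefixes <- character()

  for (i in seq_len(nrow(dump))) {
    row <- dump[i, ]
    ext <- row$external_prefix
    if (ext %in% already) {
      skipped[[length(skipped) + 1L]] <- dplyr::mutate(row, reason = "already-mapped")
      next
    }
    hit <- index_lookup(lookup, norm_key(ext))
    if (!is.na(hit) && hit %in% used_prefixes) hit <- NA_character_
    if (!is.na(hit)) {
      blocked <- any(bl$registry_key == meta$key & bl$external_prefix == ext & bl$prefix == hit)
      if (blocked) {
        skipped[[length(skipped) + 1L]] <- dplyr::mutate(row, reason = "blocklisted")
        next
      }
      mappings[[length(mappings) + 1L]] <- tibble::tibble(
        prefix = hit, registry_key = meta$key, external_prefix = ext,
        provenance = "automated"
      )
      used_prefixes <- c(used_prefixes, hit)
      next
    }
    # unmatched: policy-group dispatch
    if (group == 1L) {
      rec <- synthesize_record(row, meta$key, taken_keys)
      taken_keys <- c(taken_keys, norm_key(rec$prefix))
      new_records[[length(new_records) + 1L]] <- rec
    } else if (group == 2L) {
      curation[[length(curation) + 1L]] <- row
    } else {
      skipped[[length(skipped) + 1L]] <- dplyr::mutate(row, reason = "group-3-unmatched")
    }
  }

  structure(
    list(
      new_mappings = if (length(mappings)) dplyr::bind_rows(mappings) else
        tibble::tibble(prefix = character(), registry_key = character(),
                       external_prefix = character(), provenance = character()),
      new_records = if (length(new_records)) dplyr::bind_rows(new_records) else empty_registry(),
      curation_rows = if (length(curation)) dplyr::bind_rows(curation) else dump[0, ],
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
        dplyr::mutate(dump[0, ], reason = character()),
      registry_key = meta$key,
      policy_group = group,
      n_input = nrow(dump)
    ),
    class = "alignment_result"
  )
}

# group-1 unmatched prefixes become new records; the canonical prefix is
# the normalized external prefix, suffixed with ".<registry_key>" if that
# key is already taken (deterministic and auditable)
synthesize_record <- function(row, registry_key, taken_keys) {
  p <- norm_key(row$external_prefix)
  if (!nzchar(p)) {
    rlang::abort(sprintf("external prefix '%s' normalizes to an empty key", row$external_prefix))
  }
  if (p %in% taken_keys) p <- paste0(p, ".", registry_key)
  get_field <- function(f) if (f %in% names(row)) row[[f]] else NA_character_
  nm <- get_field("name")
  # only import well-formed optional metadata; malformed values would fail
  # the all-or-nothing QA gate in apply_result()
  fmt <- get_field("uri_format")
  if (!is.na(fmt) && count_placeholders(fmt) != 1L) fmt <- NA_character_
  pat <- get_field("pattern")
  ex <- get_field("example")
  if (!is.na(pat) && !is.na(ex) && !isTRUE(matches_pattern(pat, ex))) ex <- NA_character_
  new_record(
    prefix = p,
    name = if (is.na(nm)) row$external_prefix else nm,
    homepage = get_field("homepage"),
    description = sprintf("Record imported automatically from the '%s' registry (external prefix '%s').",
                          registry_key, row$external_prefix),
    example = ex,
    pattern = pat,
    uri_format = fmt,
    mappings = tibble::tibble(
      registry_key = registry_key, external_prefix = row$external_prefix,
      provenance = "automated"
    )
  )
}

#' Apply an alignment result to the registry
#'
#' Merges the run's automated mappings into the matched records and appends
#' the synthesized new records, then re-runs registry QA. The contract is
#' all-or-nothing: if the merged registry fails QA the original registry is
#' returned unchanged via an error. Curation rows can be written to a TSV
#' sidecar for manual review.
#'
#' @param registry the registry tibble the result was computed against.
#' @param result an [align()] result.
#' @param curation_path optional path for the curation-sheet TSV (columns
#'   `registry_key`, `external_prefix`, `name`, `homepage`, `example`,
#'   `uri_format`).
#' @return The updated registry tibble.
#' @export
apply_result <- function(registry, result, curation_path = NULL) {
  stopifnot(inherits(result, "alignment_result"))
  out <- registry
  nm <- result$new_mappings
  for (i in seq_len(nrow(nm))) {
    j <- match(nm$prefix[i], out$prefix)
    if (is.na(j)) {
      rlang::abort(sprintf("mapping target '%s' not in registry; result is stale", nm$prefix[i]))
    }
    m <- out$mappings[[j]]
    if (!any(m$registry_key == nm$registry_key[i] & m$external_prefix == nm$external_prefix[i])) {
      out$mappings[[j]] <- dplyr::bind_rows(m, nm[i, c("registry_key", "external_prefix", "provenance")])
    }
  }
  if (nrow(result$new_records)) {
    fresh <- result$new_records[!result$new_records$prefix %in% out$prefix, , drop = FALSE]
    out <- dplyr::bind_rows(out, fresh)
  }
  qa <- validate_registry(out)
  qa <- qa[!qa$check %in% "required-field", , drop = FALSE] # imported rows may be sparse
  if (nrow(qa)) {
    rlang::abort(
      paste0("post-merge QA failed; registry left unchanged: ",
             paste(unique(qa$message), collapse = "; ")),
      class = "prefixkit_qa_error"
    )
  }
  if (!is.null(curation_path)) write_curation_sheet(result, curation_path)
  out
}

#' @rdname apply_result
#' @param path output TSV path.
#' @export
write_curation_sheet <- function(result, path) {
  stopifnot(inherits(result, "alignment_result"))
  cols <- c("registry_key", "external_prefix", "name", "homepage", "example", "uri_format")
  rows <- result$curation_rows
  for (cl in setdiff(cols, names(rows))) rows[[cl]] <- NA_character_
  readr::write_tsv(rows[, cols], path, na = "")
  invisible(path)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> registry '%s' (group %d): %d rows -> %d mapped, %d new, %d curation, %d skipped\n",
    x$registry_key, x$policy_group, x$n_input, nrow(x$new_mappings),
    nrow(x$new_records), nrow(x$curation_rows), nrow(x$skipped)
  ))
  invisible(x)
}
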