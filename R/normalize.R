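#' Normalize a prefix-like string to its lookup key
#'
#' Collapses the variation observed across registries in the wild:
#' capitalization (`go` vs `GO`), and punctuation/spacing (`ec-code` vs
#' `eccode`). The key is the casefolded string with `-`, `_`, `.`, space,
#' and `/` removed.
#'
#' @param s character vector of prefix-like strings; empty or `NA` elements
#'   are an error.
#' @return Character vector of normalized keys.
#' @examples
#' norm_key(c("ec-code", "NCBITaxon", "GO")) # "eccode" "ncbitaxon" "go"
#' @export
norm_key <- function(s) {
  if (!is.character(s)) rlang::abort("norm_key() expects a character vector")
  if (length(s) == 0L) return(character())
  if (any(is.na(s) | !nzchar(s))) {
    rlang::abort("norm_key(): empty or missing input", class = "prefixkit_value_error")
  }
  gsub("[-_./ ]", "", tolower(s))
}

#' Build the prefix lookup index
#'
#' One lookup table over the whole registry, keyed by [norm_key()] of every
#' record's canonical prefix, preferred prefix, and all synonyms. The index
#' must be injective: construction fails loudly, naming both offending
#' records, if two records claim the same normalized key — the same
#' collision the registry-level QA reports as `lookup-collision`.
#'
#' @param registry a registry tibble.
#' @param exclude_registry optional external-registry key: records that
#'   already carry a mapping to that registry are left out of the index
#'   (used by [align()], which must not re-map already-mapped records).
#' @return A tibble of class `prefix_index` with columns `key`, `prefix`,
#'   `source`.
#' @export
build_prefix_index <- function(registry, exclude_registry = NULL) {
  stopifnot(is.data.frame(registry))
  if (!is.null(exclude_registry) && nrow(registry)) {
    mapped <- registry_mapping_table(registry)
    drop <- unique(mapped$prefix[mapped$registry_key %in% exclude_registry])
    registry <- registry[!registry$prefix %in% drop, , drop = FALSE]
  }
  if (!nrow(registry)) {
    idx <- tibble::tibble(key = character(), prefix = character(), source = character())
    class(idx) <- c("prefix_index", class(idx))
    return(idx)
  }
  idx <- registry_key_table(registry)
  dup <- idx$key[duplicated(idx$key)]
  if (length(dup)) {
    offenders <- idx |>
      dplyr::filter(.data$key %in% dup) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(who = paste(sort(unique(.data$prefix)), collapse = "', '"),
                       .groups = "drop")
    rlang::abort(
      paste0("prefix index collision: ",
             paste(sprintf("key '%s' claimed by records '%s'", offenders$key, offenders$who),
                   collapse = "; ")),
      class = "prefixkit_collision_error"
    )
  }
  class(idx) <- c("prefix_index", class(idx))
  idx
}

index_lookup <- function(index, keys) {
  m <- match(keys, index$key)
  index$prefix[m]
}

as_prefix_index <- function(x) {
  if (inherits(x, "prefix_index")) x else build_prefix_index(x)
}

#' Standardize a prefix string against the registry
#'
#' Maps any capitalization/punctuation/synonym variant of a prefix to its
#' canonical form (e.g. `"taxonomy"`, `"NCBITAXON"`, and `"NCBI_taxid"` all
#' standardize to `"ncbitaxon"` when those synonyms are curated). A total
#' function: unrecognized strings give `NA`, never an error.
#'
#' @param registry a registry tibble, or a prebuilt [build_prefix_index()]
#'   (pass the index when standardizing in bulk).
#' @param s character vector of prefix-like strings.
#' @return Character vector of canonical prefixes, `NA` where unrecognized.
#' @export
standardize_prefix <- function(registry, s) {
  index <- as_prefix_index(registry)
  out <- rep(NA_character_, length(s))
  ok <- !is.na(s) & nzchar(s)
  if (any(ok)) out[ok] <- index_lookup(index, norm_key(s[ok]))
  out
}

#' Standardize CURIE strings against the registry
#'
#' Splits each string on the *first* colon (local identifiers may
#' themselves contain colons), standardizes the prefix, and strips a
#' redundantly embedded namespace ("banana") exactly once: if the local
#' identifier begins with the record's canonical or preferred prefix
#' followed by `:` (case-insensitively), that token is removed, so
#' `"GO:GO:0006915"` standardizes to `go:0006915`.
#'
#' @param registry a registry tibble.
#' @param s character vector of CURIE strings; an element without a colon
#'   is a parse error (distinct from the unknown-prefix `NA` outcome).
#' @param index optional prebuilt [build_prefix_index()].
#' @return A tibble with columns `input`, `prefix`, `luid`, `curie`
#'   (`prefix` and downstream columns `NA` where the prefix is
#'   unrecognized).
#' @examples
#' reg <- example_registry()
#' standardize_curie(reg, c("GO:GO:0006915", "uniprot:P0DP23"))
#' @export
standardize_curie <- function(registry, s, index = NULL) {
  stopifnot(is.character(s))
  if (any(!grepl(":", s, fixed = TRUE))) {
    bad <- s[!grepl(":", s, fixed = TRUE)]
    rlang::abort(sprintf("not a CURIE (no ':'): %s", paste(bad, collapse = ", ")),
                 class = "prefixkit_parse_error")
  }
  index <- index %||% as_prefix_index(registry)
  raw_prefix <- sub(":.*$", "", s)
  luid <- sub("^[^:]*:", "", s)
  prefix <- standardize_prefix(index, raw_prefix)

  preferred <- registry$preferred_prefix[match(prefix, registry$prefix)]
  for (i in seq_along(s)) {
    if (is.na(prefix[i])) next
    for (tok in unique(c(prefix[i], preferred[i]))) {
      if (is.na(tok)) next
      head_ <- paste0(tok, ":")
      if (nchar(luid[i]) > nchar(head_) &&
          tolower(substring(luid[i], 1L, nchar(head_))) == tolower(head_)) {
        luid[i] <- substring(luid[i], nchar(head_) + 1L)
        break # strip at most once
      }
    }
  }
  tibble::tibble(
    input = s, prefix = prefix, luid = ifelse(is.na(prefix), NA_character_, luid),
    curie = ifelse(is.na(prefix), NA_character_, paste0(prefix, ":", luid))
  )
}

#' Render CURIEs in a chosen style
#'
#' The canonical form is lowercase (`go:0006915`); `"preferred"` uses the
#' record's stylized prefix when curated (`GO:0006915`); `"upper"` renders
#' the prefix in upper case as seen in some resources.
#'
#' @param registry a registry tibble.
#' @param prefix canonical prefix vector.
#' @param luid local unique identifier vector.
#' @param style one of `"canonical"`, `"preferred"`, `"upper"`.
#' @return Character vector of CURIEs.
#' @export
render_curie <- function(registry, prefix, luid,
                         style = c("canonical", "preferred", "upper")) {
  style <- match.arg(style)
  shown <- switch(style,
    canonical = prefix,
    upper = toupper(prefix),
    preferred = {
      pp <- registry$preferred_prefix[match(prefix, registry$prefix)]
      ifelse(is.na(pp), prefix, pp)
    }
  )
  paste0(shown, ":", luid)
}

#' Enumerate the distinct CURIE forms of one identifier
#'
#' @param registry a registry tibble.
#' @param prefix canonical prefix.
#' @param luid local unique identifier.
#' @return A tibble with columns `style`, `curie`, deduplicated on `curie`.
#' @export
curie_forms <- function(registry, prefix, luid) {
  styles <- c("canonical", "preferred", "upper")
  tibble::tibble(
    style = styles,
    curie = vapply(styles, function(st) render_curie(registry, prefix, luid, st),
                   character(1), USE.NAMES = FALSE)
  ) |>
    dplyr::distinct(.data$curie, .keep_all = TRUE)
}
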