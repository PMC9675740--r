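#' Validate local unique identifiers against a record's pattern
#'
#' An identifier is valid iff it fully matches the record's curated regular
#' expression. Records without a pattern validate vacuously — the result is
#' `TRUE` but flagged in the `"vacuous"` attribute, mirroring the partial
#' metadata reality of external registries.
#'
#' @param registry a registry tibble.
#' @param prefix canonical prefix vector (unknown prefixes are an error).
#' @param luid local unique identifier vector (recycled against `prefix`).
#' @return Logical vector with a logical `"vacuous"` attribute of the same
#'   length.
#' @examples
#' reg <- example_registry()
#' validate_identifier(reg, "pubmed", "29175850") # TRUE
#' validate_identifier(reg, "go", "GO:0006915")   # FALSE: unstandardized
#' @export
validate_identifier <- function(registry, prefix, luid) {
  n <- max(length(prefix), length(luid))
  prefix <- rep_len(prefix, n)
  luid <- rep_len(luid, n)
  m <- match(prefix, registry$prefix)
  if (anyNA(m)) {
    rlang::abort(sprintf("unknown prefix: %s", paste(unique(prefix[is.na(m)]), collapse = ", ")),
                 class = "prefixkit_key_error")
  }
  pat <- registry$pattern[m]
  vacuous <- is.na(pat)
  ok <- vacuous
  for (i in which(!vacuous)) ok[i] <- isTRUE(matches_pattern(pat[i], luid[i]))
  attr(ok, "vacuous") <- vacuous
  ok
}

record_for <- function(registry, prefix) {
  m <- match(prefix, registry$prefix)
  if (is.na(m)) {
    rlang::abort(sprintf("unknown prefix: %s", prefix), class = "prefixkit_key_error")
  }
  registry[m, ]
}

expand_format <- function(fmt, luid) {
  # bit-exact single substitution of the "$1" placeholder
  sub("$1", luid, fmt, fixed = TRUE)
}

#' Construct a URI from a standardized CURIE
#'
#' Substitutes the local identifier into a URI format string: by default
#' the record's primary `uri_format`, or a named provider's format.
#'
#' @param registry a registry tibble.
#' @param curie character vector of standardized CURIEs
#'   (`prefix:luid`).
#' @param provider optional provider code; must exist on each record.
#' @return Character vector of URIs.
#' @examples
#' reg <- example_registry()
#' curie_to_uri(reg, "uniprot:P0DP23")
#' @export
curie_to_uri <- function(registry, curie, provider = NULL) {
  parts <- split_curie(curie)
  vapply(seq_len(nrow(parts)), function(i) {
    r <- record_for(registry, parts$prefix[i])
    fmt <- if (is.null(provider)) {
      r$uri_format
    } else {
      prov <- r$providers[[1]]
      j <- match(provider, prov$code)
      if (is.na(j)) {
        rlang::abort(sprintf("record '%s' has no provider '%s'", r$prefix, provider),
                     class = "prefixkit_key_error")
      }
      prov$uri_format[j]
    }
    if (is.na(fmt)) {
      rlang::abort(sprintf("record '%s' has no URI format string: unresolvable", r$prefix),
                   class = "prefixkit_unresolvable_error")
    }
    expand_format(fmt, parts$luid[i])
  }, character(1))
}

split_curie <- function(curie) {
  stopifnot(is.character(curie))
  if (any(!grepl(":", curie, fixed = TRUE))) {
    rlang::abort("not a CURIE (no ':')", class = "prefixkit_parse_error")
  }
  tibble::tibble(
    prefix = sub(":.*$", "", curie),
    luid = sub("^[^:]*:", "", curie)
  )
}

#' Enumerate all provider URIs for one identifier
#'
#' One URI per provider on the record, in the record's provider order.
#' Providers that construct the same URI are deduplicated with a warning
#' (the first provider keeps the entry).
#'
#' @param registry a registry tibble.
#' @param curie a single standardized CURIE.
#' @return A tibble with columns `code`, `category`, `uri`.
#' @examples
#' reg <- example_registry()
#' list_provider_uris(reg, "uniprot:P0DP23")
#' @export
list_provider_uris <- function(registry, curie) {
  parts <- split_curie(curie)
  r <- record_for(registry, parts$prefix[1])
  prov <- r$providers[[1]]
  if (!nrow(prov)) {
    return(tibble::tibble(code = character(), category = character(), uri = character()))
  }
  out <- tibble::tibble(
    code = prov$code, category = prov$category,
    uri = vapply(prov$uri_format, expand_format, character(1), luid = parts$luid[1],
                 USE.NAMES = FALSE)
  )
  if (anyDuplicated(out$uri)) {
    dup <- out$code[duplicated(out$uri)]
    rlang::warn(sprintf("providers %s construct duplicate URIs for %s; deduplicated",
                        paste(dup, collapse = ", "), curie))
    out <- out[!duplicated(out$uri), , drop = FALSE]
  }
  out
}

# every invertible URI template in the registry, one row per template:
# prefix, provider code, the constant head before "$1" and tail after it
uri_template_table <- function(registry) {
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    prov <- r$providers[[1]]
    fmts <- tibble::tibble(
      code = c("default", prov$code),
      uri_format = c(r$uri_format, prov$uri_format)
    )
    fmts <- fmts[!is.na(fmts$uri_format), , drop = FALSE]
    fmts <- fmts[vapply(fmts$uri_format, count_placeholders, integer(1)) == 1L, , drop = FALSE]
    if (!nrow(fmts)) return(NULL)
    pos <- regexpr(PLACEHOLDER, fmts$uri_format, fixed = TRUE)
    tibble::tibble(
      prefix = r$prefix,
      code = fmts$code,
      head = substring(fmts$uri_format, 1L, pos - 1L),
      tail = substring(fmts$uri_format, pos + nchar(PLACEHOLDER))
    )
  })
}

#' Parse URIs back into CURIEs
#'
#' Matches each URI against every known URI prefix in the registry (primary
#' format strings and all providers). When several templates match, the
#' longest URI prefix wins; remaining ties break lexicographically by
#' canonical prefix. The remainder of the URI becomes the local identifier.
#'
#' @param registry a registry tibble.
#' @param uri character vector of URIs.
#' @return A tibble with columns `uri`, `prefix`, `luid`, `curie` (`NA`
#'   rows where no URI prefix matches).
#' @examples
#' reg <- example_registry()
#' parse_uri(reg, "http://purl.obolibrary.org/obo/CHEBI_1234")
#' @export
parse_uri <- function(registry, uri) {
  tpl <- uri_template_table(registry)
  out <- tibble::tibble(uri = uri, prefix = NA_character_, luid = NA_character_,
                        curie = NA_character_)
  if (is.null(tpl) || !nrow(tpl)) return(out)
  for (i in seq_along(uri)) {
    u <- uri[i]
    hit <- startsWith(u, tpl$head) & endsWith(u, tpl$tail) &
      nchar(u) > nchar(tpl$head) + nchar(tpl$tail)
    if (!any(hit)) next
    cand <- tpl[hit, , drop = FALSE]
    cand <- cand[order(-nchar(cand$head), cand$prefix), , drop = FALSE]
    best <- cand[1, ]
    out$prefix[i] <- best$prefix
    out$luid[i] <- substring(u, nchar(best$head) + 1L, nchar(u) - nchar(best$tail))
    out$curie[i] <- paste0(best$prefix, ":", out$luid[i])
  }
  out
}
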