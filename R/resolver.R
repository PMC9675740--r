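#' Resolve a CURIE to a provider URL
#'
#' Standardizes the CURIE (synonyms, casing, redundant namespaces),
#' validates the local identifier against the record's pattern (a failure
#' is a warning, not an error — the URL is still constructed), then returns
#' the URI from the highest-ranked available provider. The record's primary
#' `uri_format` counts as its default first-party provider; within a
#' category the record's provider order is respected.
#'
#' @param registry a registry tibble.
#' @param curie_string a single CURIE string in any recognized variant.
#' @param provider_rank preference order over provider categories.
#' @return A single URL string.
#' @examples
#' reg <- example_registry()
#' resolve_curie(reg, "TAXONOMY:9606")
#' @export
resolve_curie <- function(registry, curie_string,
                          provider_rank = c("first-party", "third-party", "resolver")) {
  std <- standardize_curie(registry, curie_string)
  if (is.na(std$prefix[1])) {
    rlang::abort(sprintf("cannot resolve '%s': unknown prefix", curie_string),
                 class = "prefixkit_resolution_error")
  }
  r <- record_for(registry, std$prefix[1])
  ok <- validate_identifier(registry, std$prefix[1], std$luid[1])
  if (!ok) {
    rlang::warn(sprintf("identifier '%s' does not match the pattern for '%s'",
                        std$luid[1], std$prefix[1]))
  }
  prov <- r$providers[[1]]
  candidates <- dplyr::bind_rows(
    if (!is.na(r$uri_format)) tibble::tibble(code = "default", category = "first-party",
                                             uri_format = r$uri_format),
    prov[, c("code", "category", "uri_format")]
  )
  candidates <- candidates[!is.na(candidates$uri_format), , drop = FALSE]
  if (is.null(candidates) || !nrow(candidates)) {
    rlang::abort(sprintf("record '%s' has no provider: unresolvable", r$prefix),
                 class = "prefixkit_unresolvable_error")
  }
  for (cat in provider_rank) {
    hit <- which(candidates$category == cat)
    if (length(hit)) return(expand_format(candidates$uri_format[hit[1]], std$luid[1]))
  }
  # categories outside the requested ranking, in record order
  expand_format(candidates$uri_format[1], std$luid[1])
}

#' Check homepage and URI-format liveness over the whole registry
#'
#' Emulates a scheduled health report: for every record, the homepage and
#' the URI built from the record's example identifier are probed with a
#' caller-supplied fetch function, so the check is fully testable offline.
#' A 4xx/5xx status or a raised condition marks the check failed;
#' redirects (3xx) count as accessible. Records without a homepage (or
#' without both an example and a URI format) get `NA` for that check.
#'
#' @param registry a registry tibble.
#' @param fetch `function(url) -> integer HTTP status`; may signal an error
#'   (treated as a connection failure).
#' @param checked_at timestamp stored on the report.
#' @return An object of class `health_report` with a per-record tibble
#'   (`prefix`, `homepage`, `homepage_ok`, `uri`, `uri_ok`, `checked_at`);
#'   see [glance.health_report()] for the summary counts.
#' @examples
#' reg <- example_registry()
#' report <- health_check(reg, fetch = function(url) 200L)
#' glance(report)
#' @export
health_check <- function(registry, fetch, checked_at = Sys.time()) {
  stopifnot(is.function(fetch))
  probe <- function(url) {
    if (is.na(url)) return(NA)
    status <- tryCatch(fetch(url), error = function(e) NA_integer_)
    if (is.na(status)) FALSE else status < 400L
  }
  uris <- vapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    if (is.na(r$uri_format) || is.na(r$example)) NA_character_
    else expand_format(r$uri_format, r$example)
  }, character(1))
  records <- tibble::tibble(
    prefix = registry$prefix,
    homepage = registry$homepage,
    homepage_ok = vapply(registry$homepage, probe, logical(1), USE.NAMES = FALSE),
    uri = uris,
    uri_ok = vapply(uris, probe, logical(1), USE.NAMES = FALSE),
    checked_at = checked_at
  )
  structure(list(records = records, checked_at = checked_at), class = "health_report")
}

#' @export
print.health_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<health_report> %d record(s): %d homepage failure(s), %d URI failure(s)\n",
              g$n_records, g$homepage_fail, g$uri_fail))
  invisible(x)
}

#' @method tidy health_report
#' @export
tidy.health_report <- function(x, ...) x$records

#' Summary counts of a health report
#'
#' Counts are a pure function of the per-record flags.
#'
#' @param x a [health_check()] report.
#' @param ... unused.
#' @return A one-row tibble of counts.
#' @method glance health_report
#' @export
glance.health_report <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    n_records = nrow(r),
    homepage_ok = sum(r$homepage_ok, na.rm = TRUE),
    homepage_fail = sum(!r$homepage_ok, na.rm = TRUE),
    homepage_unchecked = sum(is.na(r$homepage_ok)),
    uri_ok = sum(r$uri_ok, na.rm = TRUE),
    uri_fail = sum(!r$uri_ok, na.rm = TRUE),
    uri_unchecked = sum(is.na(r$uri_ok))
  )
}

#' Write a health report as JSON plus a Markdown status table
#'
#' The Markdown table color-codes each check with a status symbol
#' (pass / fail / unchecked).
#'
#' @param report a [health_check()] report.
#' @param json_path,md_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_health_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "health_report"))
  if (!is.null(json_path)) {
    payload <- list(
      checked_at = format(report$checked_at, "%Y-%m-%dT%H:%M:%S%z"),
      summary = as.list(glance(report)),
      records = report$records[, c("prefix", "homepage_ok", "uri_ok")]
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  if (!is.null(md_path)) {
    badge <- function(ok) ifelse(is.na(ok), "⚪ unchecked",
                                 ifelse(ok, "\U0001F7E2 ok", "\U0001F534 fail"))
    lines <- c(
      "| prefix | homepage | example URI |",
      "| --- | --- | --- |",
      sprintf("| %s | %s | %s |", report$records$prefix,
              badge(report$records$homepage_ok), badge(report$records$uri_ok))
    )
    writeLines(lines, md_path)
  }
  invisible(report)
}
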