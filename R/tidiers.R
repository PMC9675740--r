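#' Tidy an alignment result into one row per dump row
#'
#' @param x an [align()] result.
#' @param ... unused.
#' @return A tibble with columns `registry_key`, `external_prefix`,
#'   `disposition` (`mapped` / `new-record` / `curation` / `skipped`),
#'   `prefix` (the matched or synthesized record, `NA` otherwise), and
#'   `reason` (for skipped rows).
#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      registry_key = x$new_mappings$registry_key,
      external_prefix = x$new_mappings$external_prefix,
      disposition = "mapped",
      prefix = x$new_mappings$prefix,
      reason = NA_character_
    ),
    tibble::tibble(
      registry_key = rep(x$registry_key, nrow(x$new_records)),
      external_prefix = purrr::map_chr(x$new_records$mappings, function(m) m$external_prefix[1]),
      disposition = "new-record",
      prefix = x$new_records$prefix,
      reason = NA_character_
    ),
    tibble::tibble(
      registry_key = x$curation_rows$registry_key,
      external_prefix = x$curation_rows$external_prefix,
      disposition = "curation",
      prefix = NA_character_,
      reason = NA_character_
    ),
    tibble::tibble(
      registry_key = x$skipped$registry_key,
      external_prefix = x$skipped$external_prefix,
      disposition = "skipped",
      prefix = NA_character_,
      reason = x$skipped$reason
    )
  )
}

#' One-row summary of an alignment run
#'
#' @param x an [align()] result.
#' @param ... unused.
#' @return A one-row tibble of bookkeeping counts; `n_input` always equals
#'   the sum of the four outcome counts (the partition property).
#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble::tibble(
    registry_key = x$registry_key,
    policy_group = x$policy_group,
    n_input = x$n_input,
    n_mapped = nrow(x$new_mappings),
    n_new_records = nrow(x$new_records),
    n_curation = nrow(x$curation_rows),
    n_skipped = nrow(x$skipped)
  )
}

#' Plot the disposition of an alignment run
#'
#' @param object an [align()] result.
#' @param ... unused.
#' @return A ggplot bar chart of dump-row dispositions.
#' @method autoplot alignment_result
#' @export
autoplot.alignment_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$disposition, fill = .data$disposition)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("Alignment of registry '%s'", object$registry_key),
      x = NULL, y = "dump rows"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a registry health report
#'
#' @param object a [health_check()] report.
#' @param ... unused.
#' @return A ggplot tile chart, one row per record, one column per check.
#' @method autoplot health_report
#' @export
autoplot.health_report <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select("prefix", homepage = "homepage_ok", `example URI` = "uri_ok") |>
    tidyr::pivot_longer(-"prefix", names_to = "check", values_to = "ok")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$check, y = .data$prefix, fill = .data$ok)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
      na.value = "grey85", name = "accessible"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Registry health report") +
    ggplot2::theme_minimal()
}
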