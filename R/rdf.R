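RDF_NS <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  dcterms = "http://purl.org/dc/terms/",
  foaf = "http://xmlns.com/foaf/0.1/",
  skos = "http://www.w3.org/2004/02/skos/core#",
  pks = "https://w3id.org/prefixkit/schema#",
  pkr = "https://w3id.org/prefixkit/resource/"
)

iri <- function(ns, local) paste0(RDF_NS[[ns]], local)

#' The registry as an RDF triple table
#'
#' The schema reuses common Semantic Web vocabularies (RDFS labels, Dublin
#' Core descriptions, FOAF homepages, SKOS alternative labels) plus a small
#' purpose-built vocabulary for registry-specific terms (prefix, identifier
#' pattern, URI format, dependency, replacement, cross-registry mapping).
#' Every record yields at least a type, label, and description triple;
#' class/property declarations are emitted even for an empty registry.
#'
#' @param registry a registry tibble.
#' @return A tibble with columns `s`, `p`, `o`, `o_type` (`"iri"` or
#'   `"literal"`), deduplicated and sorted.
#' @export
registry_triples <- function(registry) {
  t_iri <- function(s, p, o) tibble::tibble(s = s, p = p, o = o, o_type = "iri")
  t_lit <- function(s, p, o) tibble::tibble(s = s, p = p, o = o, o_type = "literal")

  out <- list(
    t_iri(iri("pks", "Resource"), iri("rdf", "type"), iri("rdfs", "Class")),
    t_lit(iri("pks", "Resource"), iri("rdfs", "label"), "Identifier resource"),
    t_iri(iri("pks", "hasPattern"), iri("rdf", "type"), iri("rdf", "Property")),
    t_iri(iri("pks", "hasUriFormat"), iri("rdf", "type"), iri("rdf", "Property")),
    t_iri(iri("pks", "dependsOn"), iri("rdf", "type"), iri("rdf", "Property"))
  )
  add <- function(x) out[[length(out) + 1L]] <<- x

  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    s <- iri("pkr", r$prefix)
    add(t_iri(s, iri("rdf", "type"), iri("pks", "Resource")))
    add(t_lit(s, iri("rdfs", "label"), if (is.na(r$name)) r$prefix else r$name))
    add(t_lit(s, iri("dcterms", "description"),
              if (is.na(r$description)) "" else r$description))
    add(t_lit(s, iri("pks", "hasPrefix"), r$prefix))
    if (!is.na(r$preferred_prefix)) add(t_lit(s, iri("pks", "hasPreferredPrefix"), r$preferred_prefix))
    if (!is.na(r$homepage)) add(t_iri(s, iri("foaf", "homepage"), r$homepage))
    if (!is.na(r$pattern)) add(t_lit(s, iri("pks", "hasPattern"), r$pattern))
    if (!is.na(r$example)) add(t_lit(s, iri("pks", "hasExample"), r$example))
    if (!is.na(r$uri_format)) add(t_lit(s, iri("pks", "hasUriFormat"), r$uri_format))
    if (isTRUE(r$deprecated)) add(t_lit(s, iri("pks", "isDeprecated"), "true"))
    if (!is.na(r$replaced_by)) add(t_iri(s, iri("pks", "isReplacedBy"), iri("pkr", r$replaced_by)))
    for (syn in r$synonyms[[1]]) add(t_lit(s, iri("skos", "altLabel"), syn))
    for (dep in r$depends_on[[1]]) add(t_iri(s, iri("pks", "dependsOn"), iri("pkr", dep)))
    m <- r$mappings[[1]]
    for (j in seq_len(nrow(m))) {
      add(t_lit(s, iri("pks", "hasMapping"),
                paste0(m$registry_key[j], ":", m$external_prefix[j])))
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$s, .data$p, .data$o_type, .data$o)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", `\\` = "\\", `"` = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

compact_iri <- function(x) {
  for (pfx in names(RDF_NS)) {
    base <- RDF_NS[[pfx]]
    hit <- startsWith(x, base)
    x[hit] <- paste0(pfx, ":", substring(x[hit], nchar(base) + 1L))
  }
  x
}

expand_iri <- function(x) {
  for (pfx in names(RDF_NS)) {
    head_ <- paste0(pfx, ":")
    hit <- startsWith(x, head_)
    x[hit] <- paste0(RDF_NS[[pfx]], substring(x[hit], nchar(head_) + 1L))
  }
  x
}

#' Serialize the registry to RDF
#'
#' The same triple set (see [registry_triples()]) is serialized to the
#' requested syntax; the outputs are deterministic (sorted triples) and
#' mutually consistent — parsing any of them with [parse_rdf()] recovers
#' the identical triple multiset.
#'
#' @param registry a registry tibble.
#' @param syntax one of `"ntriples"`, `"turtle"`, `"jsonld"`.
#' @return A single character string holding the serialized graph.
#' @export
export_rdf <- function(registry, syntax = c("ntriples", "turtle", "jsonld")) {
  if (length(syntax) == 1L && !syntax %in% c("ntriples", "turtle", "jsonld")) {
    rlang::abort(sprintf("unsupported RDF syntax: %s", syntax),
                 class = "prefixkit_config_error")
  }
  syntax <- match.arg(syntax)
  tr <- registry_triples(registry)
  switch(syntax,
    ntriples = serialize_ntriples(tr),
    turtle = serialize_turtle(tr),
    jsonld = serialize_jsonld(tr)
  )
}

serialize_ntriples <- function(tr) {
  obj <- ifelse(tr$o_type == "iri",
                paste0("<", tr$o, ">"),
                paste0("\"", escape_literal(tr$o), "\""))
  paste0(paste0("<", tr$s, "> <", tr$p, "> ", obj, " .", collapse = "\n"), "\n")
}

serialize_turtle <- function(tr) {
  header <- paste0("@prefix ", names(RDF_NS), ": <", unname(RDF_NS), "> .", collapse = "\n")
  obj <- ifelse(tr$o_type == "iri",
                compact_iri(tr$o),
                paste0("\"", escape_literal(tr$o), "\""))
  obj <- ifelse(tr$o_type == "iri" & !grepl("^[a-z]+:[^/<>]*$", obj), paste0("<", tr$o, ">"), obj)
  body <- paste0(compact_iri(tr$s), " ", compact_iri(tr$p), " ", obj, " .", collapse = "\n")
  paste0(header, "\n\n", body, "\n")
}

serialize_jsonld <- function(tr) {
  graph <- lapply(split(seq_len(nrow(tr)), tr$s)[unique(tr$s)], function(ix) {
    node <- list(`@id` = tr$s[ix[1]])
    for (p in unique(tr$p[ix])) {
      jx <- ix[tr$p[ix] == p]
      vals <- lapply(jx, function(j) {
        if (tr$o_type[j] == "iri") list(`@id` = tr$o[j]) else list(`@value` = tr$o[j])
      })
      node[[p]] <- vals
    }
    node
  })
  as.character(jsonlite::toJSON(list(`@graph` = unname(graph)), auto_unbox = TRUE, pretty = TRUE))
}

#' Parse RDF produced by [export_rdf()] back into a triple table
#'
#' Minimal parsers covering the subset of each syntax that [export_rdf()]
#' emits; used to verify cross-syntax consistency of the exports.
#'
#' @param text serialized graph string.
#' @param syntax one of `"ntriples"`, `"turtle"`, `"jsonld"`.
#' @return A triple tibble as in [registry_triples()] (sorted).
#' @export
parse_rdf <- function(text, syntax = c("ntriples", "turtle", "jsonld")) {
  syntax <- match.arg(syntax)
  tr <- switch(syntax,
    ntriples = parse_ntriples(text),
    turtle = parse_turtle(text),
    jsonld = parse_jsonld(text)
  )
  dplyr::arrange(tr, .data$s, .data$p, .data$o_type, .data$o)
}

parse_ntriples <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec('^<([^>]*)> <([^>]*)> (.*) \\.$', lines))
  purrr::map_dfr(m, function(g) {
    obj <- g[4]
    if (startsWith(obj, "<")) {
      tibble::tibble(s = g[2], p = g[3], o = substring(obj, 2L, nchar(obj) - 1L), o_type = "iri")
    } else {
      tibble::tibble(s = g[2], p = g[3],
                     o = unescape_literal(substring(obj, 2L, nchar(obj) - 1L)),
                     o_type = "literal")
    }
  })
}

parse_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "@prefix")]
  term <- function(x) {
    if (startsWith(x, "<")) substring(x, 2L, nchar(x) - 1L) else expand_iri(x)
  }
  purrr::map_dfr(lines, function(ln) {
    stopifnot(endsWith(ln, " ."))
    ln <- substring(ln, 1L, nchar(ln) - 2L)
    sp <- regexec("^(\\S+) (\\S+) (.*)$", ln)
    g <- regmatches(ln, sp)[[1]]
    obj <- g[4]
    if (startsWith(obj, "\"")) {
      tibble::tibble(s = term(g[2]), p = term(g[3]),
                     o = unescape_literal(substring(obj, 2L, nchar(obj) - 1L)),
                     o_type = "literal")
    } else {
      tibble::tibble(s = term(g[2]), p = term(g[3]), o = term(obj), o_type = "iri")
    }
  })
}

parse_jsonld <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  purrr::map_dfr(doc$`@graph`, function(node) {
    s <- node$`@id`
    preds <- setdiff(names(node), "@id")
    purrr::map_dfr(preds, function(p) {
      purrr::map_dfr(node[[p]], function(v) {
        if (!is.null(v$`@id`)) {
          tibble::tibble(s = s, p = p, o = v$`@id`, o_type = "iri")
        } else {
          tibble::tibble(s = s, p = p, o = v$`@value`, o_type = "literal")
        }
      })
    })
  })
}
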