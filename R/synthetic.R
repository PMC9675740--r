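SYLLABLES <- c(
  "bio", "gen", "chem", "prot", "cell", "tax", "path", "enz", "seq",
  "omic", "lig", "meta", "reg", "var", "loc", "imm", "neur", "micro"
)

#' Perturbation profile for synthetic external-registry dumps
#'
#' Controls how a dump derived from a truth registry distorts each prefix
#' and which metadata fields are dropped, emulating the heterogeneity seen
#' across real registries: capitalization variants, punctuation variants,
#' synonym substitution, genuinely novel entries, and partial per-field
#' metadata coverage.
#'
#' @param casing_rate probability a prefix gets a casing change.
#' @param punctuation_rate probability a punctuation character is inserted
#'   (the result differs from the canonical prefix but shares its
#'   [norm_key()]).
#' @param synonym_swap_rate probability the prefix is replaced by one of
#'   the record's curated synonyms.
#' @param novel_rate governs novel rows: each truth record is emitted with
#'   probability `1 - novel_rate`, and `ceiling(novel_rate * n)` novel rows
#'   with no counterpart in the truth registry are appended.
#' @param field_dropout named numeric vector of per-field drop
#'   probabilities over `name`, `homepage`, `example`, `pattern`,
#'   `uri_format`.
#' @return A list of class `perturb_profile`.
#' @export
perturb_profile <- function(casing_rate = 0.3, punctuation_rate = 0.2,
                            synonym_swap_rate = 0.1, novel_rate = 0.1,
                            field_dropout = c(name = 0, homepage = 0.2,
                                              example = 0.4, pattern = 0.5,
                                              uri_format = 0.3)) {
  rates <- c(casing_rate, punctuation_rate, synonym_swap_rate, novel_rate, field_dropout)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("all perturbation rates must lie in [0, 1]",
                 class = "prefixkit_value_error")
  }
  structure(
    list(casing_rate = casing_rate, punctuation_rate = punctuation_rate,
         synonym_swap_rate = synonym_swap_rate, novel_rate = novel_rate,
         field_dropout = field_dropout),
    class = "perturb_profile"
  )
}

#' Generate a ground-truth registry
#'
#' Builds a collision-free registry of `n` synthetic identifier resources,
#' each with a pronounceable stem, a zero-padded numeric tag that
#' guarantees distinct normalized keys, `synonyms_per_record` synonyms
#' (letter-suffixed, so they can never collide with a canonical prefix), a
#' digit pattern with a matching example, a first-party URI format ending
#' in the placeholder, and a resolver provider. Deterministic for a fixed
#' seed; the generated registry passes [validate_registry()] by
#' construction.
#'
#' Draw order per record: stem syllables, preferred-prefix coin, pattern
#' width, example digits, then synonym stems.
#'
#' @param n number of records (`>= 1`).
#' @param synonyms_per_record synonyms per record (0 or more).
#' @param seed integer seed governing all randomness.
#' @return A list of class `truth_set` with elements `registry` and `seed`.
#' @export
generate_truth <- function(n, synonyms_per_record = 2, seed = 1) {
  stopifnot(n >= 1, synonyms_per_record >= 0)
  width <- nchar(as.character(n))
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      stem <- paste(sample(SYLLABLES, 2, replace = TRUE), collapse = "")
      tag <- formatC(i, width = width, flag = "0")
      prefix <- paste0(stem, tag)
      preferred <- if (stats::runif(1) < 0.5) toupper(prefix) else NA_character_
      k <- sample(4:8, 1)
      example <- paste(sample(0:9, k, replace = TRUE), collapse = "")
      synonyms <- if (synonyms_per_record > 0) {
        vapply(seq_len(synonyms_per_record), function(j) {
          alt <- paste(sample(SYLLABLES, 1), collapse = "")
          paste0(alt, tag, letters[j])
        }, character(1))
      } else {
        character()
      }
      new_record(
        prefix = prefix,
        preferred_prefix = preferred,
        name = paste0(toupper(substring(stem, 1, 1)), substring(stem, 2), " Resource ", i),
        homepage = sprintf("https://%s.example.org", prefix),
        description = sprintf("Synthetic identifier resource %d with stem '%s'.", i, stem),
        synonyms = synonyms,
        pattern = sprintf("^\\d{%d}$", k),
        example = example,
        uri_format = sprintf("https://%s.example.org/entry/$1", prefix),
        providers = dplyr::bind_rows(
          provider("self", sprintf("%s site", prefix),
                   sprintf("https://%s.example.org/entry/$1", prefix), "first-party"),
          provider("rsv", "Example resolver",
                   sprintf("https://resolver.example.org/%s:$1", prefix), "resolver")
        )
      )
    })
    structure(list(registry = dplyr::bind_rows(recs), seed = seed),
              class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d record(s), seed %d\n", nrow(x$registry), x$seed))
  invisible(x)
}

insert_punct <- function(s) {
  pos <- sample(seq_len(nchar(s) - 1L), 1)
  paste0(substring(s, 1, pos), sample(c("-", "_", "."), 1), substring(s, pos + 1L))
}

recase <- function(s) {
  mode <- sample(c("upper", "title"), 1)
  out <- switch(mode,
    upper = toupper(s),
    title = paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  )
  if (identical(out, s)) toupper(s) else out
}

#' Derive a perturbed external-registry dump from a truth set
#'
#' Each truth record is emitted with probability `1 - novel_rate` under a
#' prefix perturbed per the profile (synonym swap first, then punctuation
#' insertion, then casing — a pipeline mirroring how variants arise in the
#' wild), with metadata fields dropped per `field_dropout`. Afterwards
#' `ceiling(novel_rate * n)` novel rows are appended, their nonsense
#' prefixes rejection-sampled to be disjoint from every truth key, and the
#' dump rows are shuffled. The planted map records the intended equivalence
#' of every mappable row.
#'
#' Draw order: per-record inclusion coins, then per emitted record the
#' swap/punctuation/casing coins and field-dropout coins, then novel-row
#' generation, then the final shuffle.
#'
#' @param truth a [generate_truth()] result.
#' @param registry_key key under which the dump pretends to originate.
#' @param profile a [perturb_profile()].
#' @param seed integer seed (independent of the truth seed).
#' @return A list of class `dump_set`: `dump` (external-record tibble),
#'   `planted` (tibble `registry_key`, `external_prefix`, `prefix`).
#' @export
derive_dump <- function(truth, registry_key, profile = perturb_profile(), seed = 1) {
  stopifnot(inherits(truth, "truth_set"), inherits(profile, "perturb_profile"))
  reg <- truth$registry
  n <- nrow(reg)
  truth_keys <- norm_key(unlist(c(reg$prefix,
                                  reg$preferred_prefix[!is.na(reg$preferred_prefix)],
                                  reg$synonyms)))
  withr::with_seed(seed, {
    include <- stats::runif(n) >= profile$novel_rate
    rows <- list()
    planted <- list()
    for (i in which(include)) {
      r <- reg[i, ]
      p <- r$prefix
      if (stats::runif(1) < profile$synonym_swap_rate && length(r$synonyms[[1]])) {
        p <- sample(r$synonyms[[1]], 1)
      }
      if (stats::runif(1) < profile$punctuation_rate && nchar(p) > 1L) p <- insert_punct(p)
      if (stats::runif(1) < profile$casing_rate) p <- recase(p)
      drop <- profile$field_dropout
      keep <- function(f) {
        p_drop <- if (f %in% names(drop)) drop[[f]] else 0
        stats::runif(1) >= p_drop
      }
      rows[[length(rows) + 1L]] <- external_record(
        registry_key, p,
        name = if (keep("name")) r$name else NA_character_,
        homepage = if (keep("homepage")) r$homepage else NA_character_,
        example = if (keep("example")) r$example else NA_character_,
        pattern = if (keep("pattern")) r$pattern else NA_character_,
        uri_format = if (keep("uri_format")) r$uri_format else NA_character_
      )
      planted[[length(planted) + 1L]] <- tibble::tibble(
        registry_key = registry_key, external_prefix = p, prefix = r$prefix
      )
    }
    n_novel <- ceiling(profile$novel_rate * n)
    novel_keys <- character()
    for (j in seq_len(n_novel)) {
      repeat {
        cand <- paste0(paste(sample(SYLLABLES, 3, replace = TRUE), collapse = ""), "zz",
                       sample(100:999, 1))
        if (!norm_key(cand) %in% c(truth_keys, novel_keys)) break
      }
      novel_keys <- c(novel_keys, norm_key(cand))
      rows[[length(rows) + 1L]] <- external_record(
        registry_key, cand,
        name = paste0("Novel resource ", cand),
        homepage = sprintf("https://%s.example.org", cand)
      )
    }
    dump <- if (length(rows)) dplyr::bind_rows(rows) else
      external_record("x", "x")[0, ]
    if (nrow(dump)) dump <- dump[sample.int(nrow(dump)), , drop = FALSE]
    structure(
      list(dump = dump,
           planted = if (length(planted)) dplyr::bind_rows(planted) else
             tibble::tibble(registry_key = character(), external_prefix = character(),
                            prefix = character()),
           registry_key = registry_key, seed = seed),
      class = "dump_set"
    )
  })
}

#' @export
print.dump_set <- function(x, ...) {
  cat(sprintf("<dump_set> registry '%s': %d row(s), %d planted equivalence(s)\n",
              x$registry_key, nrow(x$dump), nrow(x$planted)))
  invisible(x)
}

#' Score an alignment run against the planted equivalence map
#'
#' Precision is the fraction of emitted mappings that agree with the
#' planted map (reported as 1 by convention when nothing was emitted);
#' recall is the fraction of planted equivalences recovered.
#'
#' @param result an [align()] result.
#' @param planted the `planted` tibble of the [derive_dump()] the result
#'   was computed on.
#' @return A one-row tibble: `precision`, `recall`, `n_emitted`,
#'   `n_planted`, `n_correct`.
#' @export
score_alignment <- function(result, planted) {
  stopifnot(inherits(result, "alignment_result"), is.data.frame(planted))
  emitted <- result$new_mappings
  correct <- nrow(dplyr::inner_join(
    emitted[, c("prefix", "registry_key", "external_prefix")],
    planted[, c("prefix", "registry_key", "external_prefix")],
    by = c("prefix", "registry_key", "external_prefix")
  ))
  tibble::tibble(
    precision = if (nrow(emitted) == 0L) 1 else correct / nrow(emitted),
    recall = if (nrow(planted) == 0L) 1 else correct / nrow(planted),
    n_emitted = nrow(emitted),
    n_planted = nrow(planted),
    n_correct = correct
  )
}
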