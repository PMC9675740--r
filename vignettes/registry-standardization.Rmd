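---
title: "Identifier registries as tidy data: the model behind prefixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifier registries as tidy data: the model behind prefixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefixkit)
```

## The data model and its assumptions

A registry is a tibble with one row per identifier resource. The required
core of a live record is a canonical prefix, a human-readable name, a
homepage, and a description; everything else — preferred (stylized) prefix,
synonyms, a local-identifier pattern with an example, URI format strings,
providers, deprecation and replacement links, dependency relations,
cross-registry mappings, attribution — is optional, mirroring the very
uneven metadata coverage of real registries. Deprecated records are kept
for posterity and only need a name and description: a resource that has
vanished from the web still needs to be interpretable in legacy data.
`proprietary` is stored but not acted upon by any exporter; we found no
principled filtering rule and prefer to leave that to consumers.

Canonical prefixes are lowercase (`^[a-z0-9][a-z0-9._-]*$`). Communities
disagree about prefix capitalization (`chebi` vs `CHEBI` vs `ChEBI`), so the
canonical form is deliberately style-free and the stylized form lives in
`preferred_prefix`. All default CURIE output is canonical lowercase;
preferred rendering is an explicit option (`render_curie(style =
"preferred")`), never a silent default, so that two pipelines using the
package always agree byte-for-byte.

URI format strings carry exactly one `$1` placeholder. A single fixed token
(rather than configurable placeholder syntax) keeps expansion a bit-exact
string substitution and makes every exporter agree on which formats are
invertible.

## Standardization

The lookup key of a prefix-like string is its casefold with `-`, `_`, `.`,
`/`, and spaces removed. This inverts exactly the two cheapest and most
common classes of variation — capitalization and punctuation — and nothing
else; synonym and vocabulary variation (`fb`, `intenz`) must be curated
explicitly. The registry-wide lookup table over canonical prefixes,
preferred prefixes, and synonyms must be injective: construction fails
loudly on collision, and the same condition is surfaced as a
`lookup-collision` violation by `validate_registry()`. Collisions are a
curation error, never resolved silently, because a resolver that guesses is
worse than one that refuses.

CURIE standardization splits on the *first* colon — local identifiers may
legitimately contain colons — and strips a redundantly embedded namespace
("banana", as in `GO:GO:0006915`) at most once, and only when the embedded
token equals the record's canonical or preferred prefix case-insensitively.
Stripping more aggressively would mangle identifiers that genuinely begin
with letters resembling a prefix.

Identifier validation is anchored: a pattern stored without `^`/`$` is
implicitly wrapped so that the whole identifier must match, which is what
rejects prefixed forms like `GO:0006915` as local identifiers. Records
without a pattern validate vacuously but the result is flagged (a `vacuous`
attribute) so callers can distinguish "checked and passed" from "nothing to
check". Content-level variation *within* an identifier scheme (the Enzyme
Commission's `1.4` vs `1.4.-.-` vs `1.4.*`) is out of scope: such variants
are detected as pattern failures, not repaired.

URI parsing matches a URI against every known template (record formats and
all providers). The longest matching URI prefix wins; remaining ties break
lexicographically by canonical prefix. Both rules exist purely for
determinism. Templates whose placeholder is not terminal are matched on
their constant head *and* tail.

## Alignment

External registries are aligned sequentially, one dump at a time, in
configured `import_order`; earlier registries win naming conflicts for
synthesized records. For one dump the algorithm is:

1. skip rows whose external prefix is already mapped for this registry;
2. look up the normalized key in the lookup table, from which records
   already mapped to this registry have been removed — an aligned run must
   never remap a record;
3. a hit becomes an automated mapping unless the (registry, external
   prefix, record) triple is blocklisted. The blocklist is consulted *only*
   on hits: it suppresses false positives and can never create a mapping;
4. misses are dispatched by the registry's policy group — 1: synthesize a
   new record from the row's metadata; 2: append to a curation sheet;
   3: skip silently.

Group membership is configuration, not inference: whether a registry's
unmatched entries deserve automatic import is an editorial judgment about
its scope and metadata quality, not something derivable from the dump.

Two in-run edge rules keep invariants intact. A second dump row whose key
hits a record already consumed earlier in the same run is routed to the
unmatched path (first hit wins), preserving the at-most-one-external-prefix
-per-registry-per-record invariant deterministically. Synthesized records
take `norm_key(external_prefix)` as their prefix, suffixed with
`.<registry_key>` when that key is already taken — a rule chosen for
determinism and auditability. Malformed optional metadata on a group-1 row
(a format without a placeholder, an example that fails its own pattern) is
dropped rather than imported.

`apply_result()` is all-or-nothing: the merged registry is re-validated and
any *structural* violation (key collisions, mapping duplicates, dangling
references) aborts the merge with the original registry untouched.
Completeness violations (a sparse imported record lacking a homepage) do
not abort: they are exactly what the curation workflow exists to fix later.
Revising an automated mapping is deliberately not an in-place operation:
the supported path is to blocklist the wrong triple and re-run.

## Exports

All exporters are deterministic — sorted keys, fixed column order, LF
endings — so repeated runs are byte-identical and diffs are meaningful.

Prefix-map contexts include only non-deprecated records whose URI format
*ends* in the placeholder (only those yield a constant URI prefix).
Profiles set the casing policy: `full`/`semweb` use canonical lowercase,
`obo` uses the preferred prefix where curated. URI-prefix collisions are an
error in strict mode; in non-strict mode the first entry in prefix order is
kept with a warning, because a best-effort context is more useful to
downstream consumers than none.

SSSOM rows bind the predicate to `skos:exactMatch` and the justification to
`semapv:ManualMappingCuration`; the format prescribes the columns but not
the vocabulary, and these are the conventional bindings for curated
equivalences. The RDF export reuses RDFS/Dublin Core/FOAF/SKOS terms and a
small purpose-built vocabulary for registry-specific properties; since no
canonical term list exists for this schema we kept it minimal (type, label,
description, homepage, prefix, pattern, example, URI format, deprecation,
replacement, dependency, mapping). The three RDF syntaxes are serialized
from one triple table, and the test suite parses each back and compares
triple sets, so cross-syntax consistency is verified rather than assumed.

## Resolution and health

`resolve_curie()` ranks providers first-party > third-party > resolver by
default — the resource's own pages are the most authoritative landing
place. Pattern failures during resolution warn but still construct the URL:
a wrong-looking identifier is often still resolvable, and refusing helps
nobody. The health check takes the fetch function as an argument; the test
suite injects stubs and never touches the network. Timeouts and retry
policy belong to the injected fetcher. 3xx responses count as accessible —
redirects are routine for long-lived resources and are exactly what
resolvers rely on.

## The synthetic-fixture generator

`generate_truth(n, synonyms_per_record, seed)` emulates the *structure* of
a curated registry: pronounceable stems with zero-padded numeric tags
(which makes every normalized key distinct by construction, so the truth
registry is collision-free), per-record digit patterns with matching
examples, first-party URI formats ending in the placeholder, and a resolver
provider. `derive_dump()` then emulates the heterogeneity observed across
real registries: casing changes, punctuation insertion (which leaves the
normalized key unchanged — precisely the variation the lookup inverts),
synonym substitution drawn from the curated synonyms, per-field metadata
dropout mirroring partially-populated registry schemas, and
`ceiling(novel_rate * n)` genuinely novel rows whose prefixes are
rejection-sampled to be disjoint from every truth key. A single integer
seed governs all randomness and the draw order is documented, so counts are
reproducible.

Default rates (casing 0.3, punctuation 0.2, synonym swap 0.1, novel 0.1,
dropout between 0 and 0.5 by field) were chosen once as a plausible mix for
a mid-quality registry and are not tuned to any test.

What the generator does *not* emulate: semantic near-duplicates (two real
resources with legitimately similar names), vocabulary variants outside the
curated synonym set, identifier-content variation, registry-specific record
structure, or growth over time. Passing the recovery suites therefore shows
that the engine inverts casing/punctuation/synonym variation exactly and
never fabricates a mapping — it does not show that real-registry alignment
needs no manual curation; the curation sheet and blocklist exist precisely
because it does.

## Problem sizes and numerical choices

The test and acceptance suites use 1,000 synthetic records for round-trip
properties, 200-record dumps across ten seeds for alignment recovery, and
30–80-record registries for idempotence and QA property loops — sizes at
which every property is exercised well away from boundary effects while the
full suite stays fast enough to run on every change. There are no floating
-point tolerances anywhere: every comparison in the package is on strings,
counts, or exact rational precision/recall values.

## Known limitations

* Ingestion adapters for real external registries are out of scope; the
  normalized external-record table is the boundary.
* The resolver computes URLs; it does not serve redirects.
* TSV export round-trips scalar and pipe-joined list fields but not
  providers or attribution (those live in the JSON source of truth).
* Pattern handling assumes PCRE-compatible pattern sources; an invalid
  pattern is reported as a violation, not repaired.
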