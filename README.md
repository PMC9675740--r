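# prefixkit

Standardization, alignment, and export of biomedical identifier prefix
registries, as tidy data in R.

## The problem

Biomedical entities are referenced by compact identifiers (CURIEs, e.g.
`uniprot:P0DP23` for the Calmodulin-1 protein) and URIs (e.g.
`https://www.uniprot.org/uniprot/P0DP23`). In practice the *same* resource is
written many ways: `go` vs `GO`, `ec-code` vs `eccode` vs `EC` vs `intenz`,
`flybase` vs `fb`, and the NCBI Taxonomy alone circulates as `taxonomy`,
`taxon`, `NCBITAXON`, `NCBI_taxid`, and more. Some conventions even embed the
namespace redundantly in the identifier (`GO:GO:0006915`). This fragmentation
breaks data integration: two datasets about the same entities cannot be
joined until their references are standardized.

prefixkit is a toolkit for curators and data engineers who maintain a
*registry* of identifier resources — one record per resource, with a
canonical prefix, prefix synonyms, a regular-expression pattern for local
identifiers, URI format strings, and providers — and who use that registry as
an interoperability layer:

* **Standardization.** Every prefix-like string is reduced to a lookup key
  `k(s)` = casefold(s) with `- _ . / ` and spaces removed; a registry-wide
  injective lookup table over {canonical prefix} ∪ {preferred prefix} ∪
  {synonyms} maps any variant to its canonical prefix. CURIEs are split on
  the first `:`, redundant namespaces are stripped exactly once, and local
  identifiers are validated by anchored (full-string) pattern matching.
* **Alignment.** External-registry dumps are mapped onto the registry
  row-by-row: a normalized-key hit yields an automated cross-registry
  equivalence mapping; misses are dispatched by the registry's import
  policy group (1 → synthesize a new record, 2 → queue on a curation
  sheet, 3 → skip silently); a curated blocklist suppresses known-wrong
  hits. The four outcomes partition the dump exactly.
* **Export.** The registry and its cross-registry mappings (the
  *metaregistry*) serialize deterministically to JSON (source of truth, with
  a JSON Schema), TSV, SSSOM mapping tables, JSON-LD prefix-map contexts,
  and RDF (N-Triples / Turtle / JSON-LD).
* **Resolution and health.** CURIEs resolve to provider URLs by category
  rank (first-party > third-party > resolver), and a stub-injectable health
  check reports which homepages and URI formats are still alive.
* **Synthetic fixtures.** A seeded generator builds collision-free truth
  registries and perturbed dumps with planted equivalences, so alignment
  recovery (precision/recall against the planted truth) is measurable
  without any network access.

## Worked example

```r
library(prefixkit)
reg <- example_registry()

standardize_curie(reg, c("GO:GO:0006915", "TAXONOMY:9606", "EC:1.4.1.2"))
#> # A tibble: 3 × 4
#>   input         prefix    luid    curie
#>   <chr>         <chr>     <chr>   <chr>
#> 1 GO:GO:0006915 go        0006915 go:0006915
#> 2 TAXONOMY:9606 ncbitaxon 9606    ncbitaxon:9606
#> 3 EC:1.4.1.2    eccode    1.4.1.2 eccode:1.4.1.2
```

The redundant `GO:` namespace is stripped, the Identifiers.org-style
`TAXONOMY` synonym is mapped onto the canonical `ncbitaxon` record, and the
Rhea-style `EC` prefix lands on the same record as HGNC's `ec-code` would.
Aligning a small external dump sorts each row into mapped / new /
curation / skipped:

```r
dump <- dplyr::bind_rows(
  external_record("newreg", "FlyBase"),   # casing variant of a canonical prefix
  external_record("newreg", "intenz"),    # vocabulary variant curated as a synonym
  external_record("newreg", "randomont")  # unknown: queued for curation (group 2)
)
glance(align(reg, registry_meta("newreg", policy_group = 2), dump))
#> # A tibble: 1 × 7
#>   registry_key policy_group n_input n_mapped n_new_records n_curation n_skipped
#>   <chr>               <int>   <int>    <int>         <int>      <int>     <int>
#> 1 newreg                  2       3        2             0          1         0
```

`n_mapped + n_new_records + n_curation + n_skipped` always equals
`n_input`. `tidy()` on the same result gives the per-row disposition,
`apply_result()` merges it into the registry under an all-or-nothing QA
gate, and `export_sssom()` / `export_context()` / `export_rdf()` /
`export_tsv()` serialize the outcome.

A thin command-line wrapper is installed at
`system.file("cli", "prefixkit", package = "prefixkit")`:

```sh
prefixkit standardize GO:GO:0006915   # -> go:0006915
prefixkit expand chebi:1234           # -> http://purl.obolibrary.org/obo/CHEBI_1234
prefixkit align --dump dump.tsv --registry-key newreg --group 2 --dry-run
```

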