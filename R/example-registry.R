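obo_providers <- function(upper, obo_key, lower = tolower(upper)) {
  dplyr::bind_rows(
    provider("obo", "OBO PURL",
             sprintf("http://purl.obolibrary.org/obo/%s_$1", upper), "first-party"),
    provider("ols", "Ontology Lookup Service",
             sprintf("https://www.ebi.ac.uk/ols4/ontologies/%s/terms?obo_id=%s:$1", obo_key, upper),
             "third-party"),
    provider("ontobee", "OntoBee",
             sprintf("http://www.ontobee.org/ontology/%s?iri=http://purl.obolibrary.org/obo/%s_$1",
                     upper, upper),
             "third-party"),
    provider("bioregistry", "Bioregistry resolver",
             sprintf("https://bioregistry.io/%s:$1", lower), "resolver")
  )
}

#' A small worked-example registry
#'
#' A hand-curated registry of well-known identifier resources (Gene
#' Ontology, ChEBI, UniProt, NCBI Taxonomy, Enzyme Commission, FlyBase,
#' PubMed, HGNC gene groups) with the prefix synonyms, providers, and
#' cross-registry mappings needed to exercise the full toolkit: synonym
#' standardization (`taxonomy` / `NCBITAXON` / `NCBI_taxid` all denote the
#' NCBI Taxonomy; `EC` and `ec-code` both denote the Enzyme Commission),
#' redundant-namespace stripping (`GO:GO:0006915`), provider enumeration
#' for the Calmodulin-1 protein `uniprot:P0DP23` (providers loaded from a
#' synthetic provider fixture shipped with the package), and a deprecated
#' record (`hgnc.genefamily`, replaced by `hgnc.genegroup`).
#'
#' @return A registry tibble that passes [validate_registry()].
#' @examples
#' reg <- example_registry()
#' standardize_prefix(reg, c("taxonomy", "NCBITAXON", "NCBI_taxid"))
#' @export
example_registry <- function() {
  uniprot_providers <- dplyr::bind_rows(lapply(
    jsonlite::read_json(system.file("extdata", "uniprot_providers_synthetic.json",
                                    package = "prefixkit"))$providers,
    tibble::as_tibble
  ))

  dplyr::bind_rows(
    new_record(
      "go",
      preferred_prefix = "GO",
      name = "Gene Ontology",
      homepage = "http://geneontology.org",
      description = "Structured controlled vocabulary of gene functions, processes, and components.",
      synonyms = c("gont"),
      pattern = "^\\d{7}$", example = "0006915",
      uri_format = "http://purl.obolibrary.org/obo/GO_$1",
      providers = obo_providers("GO", "go"),
      depends_on = "chebi",
      mappings = tibble::tibble(
        registry_key = c("obofoundry", "miriam", "ols"),
        external_prefix = c("GO", "go", "go"),
        provenance = "curated"
      ),
      contributor = attribution("Example Curator", "0000-0002-1825-0097")
    ),
    new_record(
      "chebi",
      preferred_prefix = "CHEBI",
      name = "Chemical Entities of Biological Interest",
      homepage = "https://www.ebi.ac.uk/chebi/",
      description = "Dictionary of molecular entities focused on small chemical compounds.",
      pattern = "^\\d+$", example = "15377",
      uri_format = "http://purl.obolibrary.org/obo/CHEBI_$1",
      providers = obo_providers("CHEBI", "chebi"),
      mappings = tibble::tibble(
        registry_key = c("obofoundry", "miriam"),
        external_prefix = c("CHEBI", "chebi"),
        provenance = "curated"
      )
    ),
    new_record(
      "uniprot",
      preferred_prefix = "UniProt",
      name = "UniProt Knowledgebase",
      homepage = "https://www.uniprot.org",
      description = "Comprehensive resource of protein sequence and annotation data.",
      synonyms = c("uniprotkb", "swissprot"),
      pattern = "^[A-Z][0-9][A-Z0-9]{3}[0-9]$", example = "P0DP23",
      uri_format = "https://www.uniprot.org/uniprot/$1",
      providers = uniprot_providers,
      mappings = tibble::tibble(
        registry_key = "miriam", external_prefix = "uniprot", provenance = "curated"
      )
    ),
    new_record(
      "ncbitaxon",
      preferred_prefix = "NCBITaxon",
      name = "NCBI Taxonomy",
      homepage = "https://www.ncbi.nlm.nih.gov/taxonomy",
      description = "Curated classification and nomenclature for all organisms.",
      synonyms = c("taxonomy", "taxon", "NCBI_taxid", "NCBI_Taxon_ID", "uniprot.taxonomy"),
      pattern = "^\\d+$", example = "9606",
      uri_format = "http://purl.obolibrary.org/obo/NCBITaxon_$1",
      providers = dplyr::bind_rows(
        provider("ncbi", "NCBI Taxonomy Browser",
                 "https://www.ncbi.nlm.nih.gov/Taxonomy/Browser/wwwtax.cgi?mode=Info&id=$1",
                 "first-party"),
        provider("obo", "OBO PURL", "http://purl.obolibrary.org/obo/NCBITaxon_$1", "first-party"),
        provider("bioregistry", "Bioregistry resolver", "https://bioregistry.io/ncbitaxon:$1",
                 "resolver")
      ),
      mappings = tibble::tibble(
        registry_key = c("miriam", "bioportal", "obofoundry"),
        external_prefix = c("taxonomy", "NCBITAXON", "NCBITaxon"),
        provenance = "curated"
      )
    ),
    new_record(
      "eccode",
      preferred_prefix = "EC",
      name = "Enzyme Commission Classification",
      homepage = "https://www.enzyme-database.org",
      description = "Hierarchical numerical classification of enzyme-catalysed reactions.",
      synonyms = c("ec", "intenz", "enzyme.nomenclature"),
      pattern = "^\\d{1,2}(\\.\\d{1,3}){0,3}$", example = "1.4.1.2",
      uri_format = "https://www.enzyme-database.org/query.php?ec=$1"
    ),
    new_record(
      "flybase",
      preferred_prefix = "FlyBase",
      name = "FlyBase",
      homepage = "https://flybase.org",
      description = "Database of Drosophila genes and genomes.",
      synonyms = c("fb"),
      pattern = "^FBgn\\d{7}$", example = "FBgn0011293",
      uri_format = "https://flybase.org/reports/$1"
    ),
    new_record(
      "pubmed",
      preferred_prefix = "PubMed",
      name = "PubMed",
      homepage = "https://pubmed.ncbi.nlm.nih.gov",
      description = "Bibliographic database of biomedical literature.",
      synonyms = c("pmid"),
      pattern = "^\\d+$", example = "29175850",
      uri_format = "https://pubmed.ncbi.nlm.nih.gov/$1"
    ),
    new_record(
      "hgnc.genegroup",
      name = "HGNC Gene Groups",
      homepage = "https://www.genenames.org",
      description = "Curated groups of human genes maintained by the HGNC.",
      pattern = "^\\d+$", example = "355",
      uri_format = "https://www.genenames.org/data/genegroup/#!/group/$1"
    ),
    new_record(
      "hgnc.genefamily",
      name = "HGNC Gene Families",
      description = "Former HGNC gene family resource, superseded by gene groups.",
      pattern = "^\\d+$", example = "355",
      deprecated = TRUE,
      replaced_by = "hgnc.genegroup"
    )
  )
}

#' Example external-registry descriptors
#'
#' Descriptors for a handful of external registries spanning the three
#' import policy groups: well-curated prefix-focused registries (group 1),
#' registries whose unmatched entries are queued for manual curation
#' (group 2), and minimal-metadata registries that are skipped silently
#' (group 3). Capability flags indicate which metadata fields each
#' registry's schema supplies.
#'
#' @return A registry-meta tibble, one row per external registry, sorted
#'   by `import_order`.
#' @export
example_metaregistry <- function() {
  dplyr::bind_rows(
    registry_meta("miriam", "Identifiers.org", "https://identifiers.org",
                  policy_group = 1L, import_order = 1L,
                  has_homepage = TRUE, has_description = TRUE, has_example = TRUE,
                  has_pattern = TRUE, has_provider = TRUE),
    registry_meta("obofoundry", "OBO Foundry", "https://obofoundry.org",
                  policy_group = 1L, import_order = 2L,
                  has_homepage = TRUE, has_description = TRUE, has_license = TRUE),
    registry_meta("ols", "Ontology Lookup Service", "https://www.ebi.ac.uk/ols4",
                  policy_group = 1L, import_order = 3L,
                  has_description = TRUE, has_version = TRUE),
    registry_meta("bioportal", "BioPortal", "https://bioportal.bioontology.org",
                  policy_group = 2L, import_order = 4L,
                  has_description = TRUE, has_example = TRUE),
    registry_meta("go", "GO registry", "http://geneontology.org",
                  policy_group = 2L, import_order = 5L,
                  has_homepage = TRUE, has_provider = TRUE),
    registry_meta("prefixcc", "Prefix.cc", "https://prefix.cc",
                  policy_group = 3L, import_order = 6L)
  )
}
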