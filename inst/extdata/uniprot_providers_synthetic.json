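{
  "_comment": "Synthetic stand-in for the UniProt provider list: eight plausible first-party, third-party, and resolver URI format strings for one protein record. Constructed for testing; not transcribed from any external source.",
  "providers": [
    {"code": "uniprot", "name": "UniProt website", "uri_format": "https://www.uniprot.org/uniprot/$1", "category": "first-party"},
    {"code": "purl", "name": "UniProt PURL", "uri_format": "http://purl.uniprot.org/uniprot/$1", "category": "first-party"},
    {"code": "rest", "name": "UniProt REST (text)", "uri_format": "https://rest.uniprot.org/uniprotkb/$1.txt", "category": "first-party"},
    {"code": "ebi-proteins", "name": "EBI Proteins API", "uri_format": "https://www.ebi.ac.uk/proteins/api/proteins/$1", "category": "third-party"},
    {"code": "alphafold", "name": "AlphaFold DB", "uri_format": "https://alphafold.ebi.ac.uk/entry/$1", "category": "third-party"},
    {"code": "miriam", "name": "Identifiers.org", "uri_format": "https://identifiers.org/uniprot:$1", "category": "resolver"},
    {"code": "n2t", "name": "Name-to-Thing", "uri_format": "https://n2t.net/uniprot:$1", "category": "resolver"},
    {"code": "bioregistry", "name": "Bioregistry resolver", "uri_format": "https://bioregistry.io/uniprot:$1", "category": "resolver"}
  ]
}
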