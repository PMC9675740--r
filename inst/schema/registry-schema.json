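{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://w3id.org/prefixkit/schema/registry-schema.json",
  "title": "Identifier resource registry",
  "description": "One JSON object mapping each canonical prefix to its identifier-resource record.",
  "type": "object",
  "propertyNames": { "pattern": "^[a-z0-9][a-z0-9._-]*$" },
  "additionalProperties": { "$ref": "#/$defs/record" },
  "$defs": {
    "record": {
      "type": "object",
      "properties": {
        "preferred_prefix": { "type": "string" },
        "name": { "type": "string" },
        "homepage": { "type": "string", "format": "uri" },
        "description": { "type": "string" },
        "synonyms": { "type": "array", "items": { "type": "string" }, "uniqueItems": true },
        "pattern": { "type": "string" },
        "example": { "type": "string" },
        "uri_format": { "type": "string" },
        "providers": { "type": "array", "items": { "$ref": "#/$defs/provider" } },
        "deprecated": { "type": "boolean" },
        "proprietary": { "type": "boolean" },
        "replaced_by": { "type": "string" },
        "depends_on": { "type": "array", "items": { "type": "string" } },
        "mappings": { "type": "array", "items": { "$ref": "#/$defs/mapping" } },
        "contributor": { "$ref": "#/$defs/attribution" },
        "reviewer": { "$ref": "#/$defs/attribution" },
        "download_obo": { "type": "string", "format": "uri" },
        "download_owl": { "type": "string", "format": "uri" },
        "download_json": { "type": "string", "format": "uri" },
        "license": { "type": "string" },
        "version": { "type": "string" },
        "contact": { "type": "string" }
      },
      "required": ["name", "description"],
      "additionalProperties": false
    },
    "provider": {
      "type": "object",
      "properties": {
        "code": { "type": "string" },
        "name": { "type": "string" },
        "uri_format": { "type": "string" },
        "category": { "enum": ["first-party", "third-party", "resolver"] }
      },
      "required": ["code", "uri_format", "category"],
      "additionalProperties": false
    },
    "mapping": {
      "type": "object",
      "properties": {
        "registry_key": { "type": "string" },
        "external_prefix": { "type": "string" },
        "provenance": { "enum": ["automated", "curated"] }
      },
      "required": ["registry_key", "external_prefix"],
      "additionalProperties": false
    },
    "attribution": {
      "type": "object",
      "properties": {
        "name": { "type": "string" },
        "orcid": { "type": "string", "pattern": "^\\d{4}-\\d{4}-\\d{4}-\\d{3}[\\dX]$" }
      },
      "required": ["name"],
      "additionalProperties": false
    }
  }
}
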