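{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "vkdbe metabolite-class knowledge base",
  "description": "Descriptor range windows (H/C, O/C, DBE, carbon count) per metabolite class, as consumed by load_kb() and produced by save_kb().",
  "type": "object",
  "required": ["classes"],
  "properties": {
    "version": { "type": "string" },
    "source": { "type": "string" },
    "classes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "group", "bounds", "requires_nitrogen"],
        "properties": {
          "name": { "type": "string" },
          "group": { "enum": ["phenolic", "nitrogenous", "isoprenoid"] },
          "requires_nitrogen": { "type": "boolean" },
          "notes": { "type": "string" },
          "bounds": {
            "type": "object",
            "minProperties": 1,
            "propertyNames": { "enum": ["hc", "oc", "dbe", "c"] },
            "additionalProperties": {
              "type": "object",
              "required": ["min", "max"],
              "properties": {
                "min": { "type": "number" },
                "max": { "type": "number" },
                "provenance": { "enum": ["paper", "derived", "user"] }
              }
            }
          }
        }
      }
    }
  }
}
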