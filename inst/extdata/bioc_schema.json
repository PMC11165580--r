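{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "BioC-JSON article with stand-off enzyme annotations",
  "type": "object",
  "required": ["documents"],
  "properties": {
    "documents": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "passages"],
        "properties": {
          "id": {"type": "string"},
          "infons": {"type": "object"},
          "passages": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["offset", "text"],
              "properties": {
                "infons": {"type": "object"},
                "offset": {"type": "integer", "minimum": 0},
                "text": {"type": "string"},
                "annotations": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["text", "infons", "id", "locations"],
                    "additionalProperties": false,
                    "properties": {
                      "text": {"type": "string"},
                      "infons": {
                        "type": "object",
                        "required": ["identifier", "type", "annotator",
                                     "updated_at"],
                        "properties": {
                          "identifier": {"type": "string"},
                          "type": {"const": "enzyme"},
                          "annotator": {"type": "string"},
                          "updated_at": {"type": "string"},
                          "method": {
                            "enum": ["direct", "keyword", "abbreviation"]
                          }
                        }
                      },
                      "id": {"type": "string"},
                      "locations": {
                        "type": "array",
                        "minItems": 1,
                        "items": {
                          "type": "object",
                          "required": ["offset", "length"],
                          "properties": {
                            "offset": {"type": "integer", "minimum": 0},
                            "length": {"type": "integer", "minimum": 1}
                          }
                        }
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
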