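{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mini-aird-1.schema.json",
  "title": "mini-Aird run index",
  "type": "object",
  "required": ["format", "precision", "mode", "intensityWidth",
               "binaryFile", "totalSpectra", "blocks"],
  "properties": {
    "format": {"const": "mini-aird-1"},
    "precision": {
      "type": "object",
      "required": ["decimalPlaces"],
      "properties": {
        "decimalPlaces": {"enum": [4, 5, 6]},
        "scale": {"enum": [10000, 100000, 1000000]}
      }
    },
    "mode": {"enum": ["DDA", "DIA"]},
    "source": {"type": "string"},
    "intensityWidth": {"enum": [4, 8]},
    "binaryFile": {"type": "string"},
    "totalSpectra": {"type": "integer", "minimum": 0},
    "blocks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["blockId", "msLevel", "layerExponent", "stacks"],
        "properties": {
          "blockId": {"type": "integer", "minimum": 0},
          "msLevel": {"enum": [1, 2]},
          "precursorWindow": {
            "oneOf": [{"type": "null"},
                      {"type": "array", "items": {"type": "number"},
                       "minItems": 2, "maxItems": 2}]
          },
          "layerExponent": {"type": "integer", "minimum": 0, "maximum": 16},
          "stacks": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["offset", "mzLength", "tagLength",
                           "intensityLength", "spectrumCount",
                           "peaksPerLayer", "rt", "spectrumIds"],
              "properties": {
                "offset": {"type": "integer", "minimum": 0},
                "mzLength": {"type": "integer", "minimum": 0},
                "tagLength": {"type": "integer", "minimum": 0},
                "intensityLength": {"type": "integer", "minimum": 0},
                "spectrumCount": {"type": "integer", "minimum": 1},
                "peaksPerLayer": {"type": "array",
                                  "items": {"type": "integer", "minimum": 0}},
                "rt": {"type": "array", "items": {"type": "number"}},
                "spectrumIds": {"type": "array",
                                "items": {"type": "integer", "minimum": 0}},
                "windows": {
                  "type": "array",
                  "items": {"type": "array", "items": {"type": "number"},
                            "minItems": 2, "maxItems": 2}
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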