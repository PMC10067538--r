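{
  "$id": "genovizrec-gosling-subset",
  "title": "Gosling-grammar subset emitted by genovizrec",
  "description": "Self-contained subset of the Gosling grammar covering only the constructs the recommendation model can produce: multi-view arrangements, linear/circular/space-filling track layouts, bar/line/point/rect/text/link marks, genomic x/xe channels, quantitative y, nominal or quantitative color, navigation (overview+brush) tracks and focus+context structure. Version pinned: subset 1.0.",
  "type": "object",
  "required": ["subsetVersion", "candidate", "assembly", "arrangement", "interactivity", "views"],
  "properties": {
    "subsetVersion": {"const": "1.0"},
    "candidate": {"type": "string"},
    "assembly": {"type": "string"},
    "arrangement": {"enum": ["single", "parallel", "adjacent", "orthogonal"]},
    "interactivity": {
      "type": "array",
      "items": {"enum": ["focus_context", "coordinated"]}
    },
    "views": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "layout", "partition", "tracks"],
        "properties": {
          "id": {"type": "string"},
          "layout": {"enum": ["linear", "circular", "space_filling"]},
          "partition": {"enum": ["contiguous", "segregated"]},
          "navigation": {
            "type": "object",
            "required": ["type", "linkedView", "genomeWide"],
            "properties": {
              "type": {"const": "overview-brush"},
              "linkedView": {"type": "string"},
              "genomeWide": {"const": true}
            }
          },
          "tracks": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["id", "file", "mark", "data", "x"],
              "properties": {
                "id": {"type": "string"},
                "file": {"type": "string"},
                "attribute": {"type": "string"},
                "mark": {"enum": ["bar", "line", "point", "rect", "text", "withinLink", "betweenLink"]},
                "data": {
                  "type": "object",
                  "required": ["format", "url"],
                  "properties": {
                    "format": {"enum": ["bigwig", "bed", "bedpe", "seg", "vcf", "cooler"]},
                    "url": {"type": "string"}
                  }
                },
                "x": {
                  "type": "object",
                  "required": ["field", "type"],
                  "properties": {"field": {"const": "position"}, "type": {"const": "genomic"}}
                },
                "xe": {
                  "type": "object",
                  "required": ["field", "type"],
                  "properties": {"field": {"const": "position_end"}, "type": {"const": "genomic"}}
                },
                "y": {
                  "type": "object",
                  "required": ["field", "type"],
                  "properties": {"field": {"type": "string"}, "type": {"const": "quantitative"}}
                },
                "color": {
                  "type": "object",
                  "required": ["field", "type"],
                  "properties": {
                    "field": {"type": "string"},
                    "type": {"enum": ["nominal", "quantitative"]},
                    "range": {"type": "array", "items": {"type": "string"}}
                  }
                },
                "text": {
                  "type": "object",
                  "required": ["field", "type"],
                  "properties": {"field": {"type": "string"}, "type": {"const": "nominal"}}
                },
                "overlay": {
                  "type": "array",
                  "items": {"type": "object"}
                }
              }
            }
          }
        }
      }
    }
  },
  "notes": [
    "Genomic coordinates in emitted domains are 1-based inclusive.",
    "Data blocks are placeholder references (format + descriptor label); no payloads are read.",
    "The navigation object is the genome-wide overview/brush track attached to a view for compare and focus+context designs; it is not counted as a data track."
  ]
}
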