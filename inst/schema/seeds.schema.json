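{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "neuroprint seed geometry file",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["mode", "axis", "index", "vertices", "role", "structure_id"],
    "properties": {
      "mode": { "enum": ["sketch", "polygon", "freedraw"] },
      "axis": { "enum": ["x", "y", "z"] },
      "index": { "type": "integer", "minimum": 0,
                 "description": "0-based slice index along axis" },
      "vertices": {
        "type": "array",
        "items": { "type": "array", "minItems": 2, "maxItems": 2,
                   "items": { "type": "number" } },
        "minItems": 1,
        "description": "in-plane points in 0-based voxel-centre coordinates; sketch: polyline (>= 2), polygon: closed ring (>= 3), freedraw: explicit pixels"
      },
      "brush_radius": { "type": "integer", "minimum": 0, "default": 0,
                        "description": "Chebyshev brush radius in voxels (sketch only)" },
      "role": { "enum": ["foreground", "background"] },
      "structure_id": { "type": "integer", "minimum": 1 }
    }
  }
}
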