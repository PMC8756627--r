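{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "airdlite metadata",
  "description": "Metadata document accompanying an .aird binary block file. Structural validation is enforced by read_metadata(); this document records the contract. Unknown additional properties are accepted with a warning.",
  "type": "object",
  "required": ["version", "acquisition_mode", "instrument", "compressor_config",
               "ignore_zero_intensity", "total_spectra", "indexes"],
  "properties": {
    "version": {"type": "string"},
    "acquisition_mode": {"enum": ["COMMON", "DDA", "DIA", "PRM"]},
    "instrument": {"type": "object"},
    "compressor_config": {
      "type": "object",
      "required": ["mz_dp", "intensity_codec", "deflate_level", "pfor"],
      "properties": {
        "mz_dp": {"type": "integer", "minimum": 1, "maximum": 6},
        "intensity_codec": {"enum": ["int-zlib", "log10-zlib"]},
        "deflate_level": {"type": "integer", "minimum": 0, "maximum": 9},
        "pfor": {
          "type": "object",
          "required": ["block_size", "exception_ratio"],
          "properties": {
            "block_size": {"type": "integer", "multipleOf": 32, "maximum": 256},
            "exception_ratio": {"type": "number", "minimum": 0,
                                "exclusiveMaximum": 0.5}
          }
        }
      }
    },
    "ignore_zero_intensity": {"type": "boolean"},
    "total_spectra": {"type": "integer", "minimum": 1},
    "indexes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["level", "start_ptr", "end_ptr", "scan_nums", "rts",
                     "mz_byte_sizes", "intensity_byte_sizes"],
        "properties": {
          "level": {"enum": [1, 2]},
          "start_ptr": {"type": "integer", "minimum": 0},
          "end_ptr": {"type": "integer", "minimum": 0},
          "scan_nums": {"type": "array", "items": {"type": "integer"}},
          "rts": {"type": "array", "items": {"type": "number"},
                  "description": "seconds, non-decreasing within the block"},
          "mz_byte_sizes": {"type": "array",
                            "items": {"type": "integer", "minimum": 0}},
          "intensity_byte_sizes": {"type": "array",
                                   "items": {"type": "integer", "minimum": 0}},
          "precursor_window": {
            "type": ["array", "null"],
            "items": {"type": "number"}, "minItems": 2, "maxItems": 2
          },
          "precursor_windows": {
            "type": "array",
            "items": {"type": "array", "items": {"type": "number"},
                      "minItems": 2, "maxItems": 2},
            "description": "DDA MS2 blocks only: one window per spectrum"
          },
          "parent_scan": {"type": ["integer", "null"]}
        }
      }
    }
  }
}
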