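{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ivret report bundle",
  "description": "Machine-readable outputs written by run_pipeline(): one prepost/moderation/rmcorr JSON per outcome plus flow statistics; every file carries provenance.",
  "type": "object",
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "config_hash", "seed"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "config_hash": {"type": "string", "pattern": "^[0-9a-f]{32}$"},
        "seed": {"type": ["integer", "null"]}
      }
    },
    "prepost": {
      "type": "object",
      "required": ["provenance", "outcome", "anova", "cells", "delta_summary",
                   "epsilon", "posthoc", "ancova", "diagnostics"],
      "properties": {
        "outcome": {"type": "string"},
        "epsilon": {"const": 1},
        "anova": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["effect", "df1", "df2", "statistic", "p_value", "ges"]
          }
        },
        "posthoc": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["contrast", "estimate", "statistic", "df",
                         "p_raw", "p_adj", "d", "d_lo", "d_hi"]
          }
        }
      }
    },
    "moderation": {
      "type": "object",
      "required": ["provenance", "outcome", "moderator", "group_fits",
                   "slope", "intercept_shift"]
    },
    "rmcorr": {
      "type": "object",
      "required": ["provenance", "outcome", "x", "by_category"]
    }
  }
}
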