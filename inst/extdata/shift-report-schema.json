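{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "riskshift/shift-report/v1",
  "title": "riskshift per-session shift report",
  "type": "object",
  "required": ["report_version", "seed", "simulated", "design", "fits",
               "shift", "per_level_tests", "rt_anova"],
  "properties": {
    "report_version": {"type": "string", "const": "1"},
    "seed": {"type": "integer"},
    "simulated": {"type": "boolean"},
    "design": {
      "type": "object",
      "required": ["n_blocks", "trials_per_block", "stim_blocks",
                   "probability_levels", "risky_win_points",
                   "risky_loss_points", "safe_points", "deadline_ms"]
    },
    "fits": {
      "type": "object",
      "required": ["off", "on"],
      "additionalProperties": {
        "type": "object",
        "required": ["status", "ppc_p", "posterior", "counts"],
        "properties": {
          "status": {"enum": ["ok", "poor_fit", "unfittable"]},
          "ppc_p": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "shift": {
      "type": "object",
      "required": ["available", "flagged", "mean", "q5", "q95",
                   "prob_left_shift", "status_off", "status_on"]
    },
    "per_level_tests": {
      "type": "object",
      "required": ["cue_prob", "off_risky", "off_safe", "on_risky",
                   "on_safe", "midp", "tier", "testable"]
    },
    "rt_anova": {
      "type": "object",
      "required": ["term", "df", "sumsq", "meansq", "statistic", "p.value"]
    }
  }
}
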