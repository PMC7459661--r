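{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "scenario_sketch",
  "description": "Synthetic retrospective burnout sketch: seven perceived variable tracks on a common monthly grid plus three labelled event timelines.",
  "type": "object",
  "required": ["times", "tracks", "timelines", "mechanism"],
  "properties": {
    "times": {
      "type": "array",
      "items": {"type": "number"},
      "description": "Monthly grid, months since sketch start"
    },
    "tracks": {
      "type": "object",
      "required": [
        "amount_of_demands", "effort", "perceived_efficacy",
        "appropriateness_of_resources", "engagement", "need_for_recovery",
        "stress_responses"
      ],
      "additionalProperties": false,
      "patternProperties": {
        ".*": {"type": "array", "items": {"type": "number", "minimum": 0, "maximum": 1}}
      }
    },
    "timelines": {
      "type": "object",
      "required": ["interventions", "work_developments", "private_developments"],
      "properties": {
        "interventions": {"type": "array"},
        "work_developments": {"type": "array"},
        "private_developments": {"type": "array"}
      }
    },
    "mechanism": {"enum": ["exhaustion", "reward_withheld"]},
    "truth": {
      "type": ["object", "null"],
      "description": "Generator ground truth: build_up/crash/recovery boundaries and plateau length (absent for sketches rendered from simulations)"
    }
  }
}
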