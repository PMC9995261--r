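{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "hkcea model configuration",
  "description": "Configuration for the hyperkalaemia management cost-effectiveness model. Any parameter, setting or life table omitted here falls back to the packaged reference fixture. Parameter names must match the registry names listed by make_reference_fixture().",
  "type": "object",
  "properties": {
    "schema_version": { "type": "string", "const": "1.0" },
    "parameters": {
      "type": "object",
      "description": "Map from registry parameter name to either a bare number (mean) or an object with mean and optional se.",
      "additionalProperties": {
        "oneOf": [
          { "type": "number" },
          {
            "type": "object",
            "properties": {
              "mean": { "type": "number" },
              "se": { "type": "number", "minimum": 0 }
            },
            "required": ["mean"],
            "additionalProperties": false
          }
        ]
      }
    },
    "settings": {
      "type": "object",
      "properties": {
        "horizon_age": { "type": "number", "minimum": 40, "maximum": 120 },
        "horizon_min_alive": { "type": "number", "exclusiveMinimum": 0 },
        "half_cycle": { "type": "boolean" },
        "age_rule": { "enum": ["step", "linear"] },
        "retrigger_enabled": { "type": "boolean" },
        "baseline_age_floor": { "type": "number" },
        "max_age": { "type": "number" }
      },
      "additionalProperties": false
    },
    "life_table": {
      "oneOf": [
        {
          "type": "string",
          "description": "Path to a CSV with columns age, sex (male/female), qx; relative paths resolve against the config file."
        },
        {
          "type": "object",
          "properties": {
            "age": { "type": "array", "items": { "type": "integer" } },
            "sex": { "type": "array", "items": { "enum": ["male", "female"] } },
            "qx": { "type": "array", "items": { "type": "number", "minimum": 0, "maximum": 1 } }
          },
          "required": ["age", "sex", "qx"]
        }
      ]
    }
  },
  "additionalProperties": false
}
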