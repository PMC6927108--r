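{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://w3id.org/phido/dialogue-script.schema.json",
  "title": "Counseling dialogue script",
  "description": "Declarative source compiled into an utterance session graph. Ordering rules enforced by the loader: salutation at most once and first; valediction at most once and last.",
  "type": "object",
  "required": ["goals"],
  "properties": {
    "title": { "type": "string" },
    "goals": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["goal", "tasks"],
        "properties": {
          "goal": {
            "enum": ["Acclimate", "Communicate Benefit",
                     "Communicate Effectiveness", "Communicate Harms",
                     "Communicate Uncertainty", "Pursuit Before Exit",
                     "Conclude"]
          },
          "tasks": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["kind"],
              "properties": {
                "kind": {
                  "enum": ["salutation", "valediction",
                           "initiate_discussion", "transition_to_topic",
                           "interview_participant", "discuss_health_topic",
                           "question_answering"]
                },
                "greeting": { "type": "string" },
                "introduction": { "type": "string" },
                "farewell": { "type": "string" },
                "concluding_farewell": { "type": "string" },
                "disclaimer": { "type": "string" },
                "overview": { "type": "string" },
                "topic_options": { "type": "array", "items": { "type": "string" } },
                "transition": { "type": "string" },
                "interview_questions": { "type": "array", "items": { "type": "string" } },
                "health_items": { "type": "array", "items": { "type": "string" }, "minItems": 1 },
                "answers": { "type": "object", "additionalProperties": { "type": "string" } },
                "request_repeat": { "type": "string" },
                "confirm_prompt": { "type": "string" },
                "acknowledgment": { "type": "string" },
                "no_answer": { "type": "string" },
                "question_options": { "type": "string" },
                "examples": {
                  "type": "object",
                  "description": "Optional per-class override of participant utterance examples.",
                  "additionalProperties": { "type": "array", "items": { "type": "string" } }
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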