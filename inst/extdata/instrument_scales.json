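{
  "version": "1.0",
  "qlq_c30": {
    "global_health": {"items": [29, 30], "range": 6, "type": "global", "direction": "higher_is_better"},
    "physical_functioning": {"items": [1, 2, 3, 4, 5], "range": 3, "type": "functional", "direction": "higher_is_better"},
    "role_functioning": {"items": [6, 7], "range": 3, "type": "functional", "direction": "higher_is_better"},
    "emotional_functioning": {"items": [21, 22, 23, 24], "range": 3, "type": "functional", "direction": "higher_is_better"},
    "cognitive_functioning": {"items": [20, 25], "range": 3, "type": "functional", "direction": "higher_is_better"},
    "social_functioning": {"items": [26, 27], "range": 3, "type": "functional", "direction": "higher_is_better"},
    "fatigue": {"items": [10, 12, 18], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "nausea_vomiting": {"items": [14, 15], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "pain": {"items": [9, 19], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "dyspnoea": {"items": [8], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "insomnia": {"items": [11], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "appetite_loss": {"items": [13], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "constipation": {"items": [16], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "diarrhoea": {"items": [17], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "financial_difficulties": {"items": [28], "range": 3, "type": "symptom", "direction": "higher_is_worse"}
  },
  "pan26": {
    "pancreatic_pain": {"items": [1, 2, 4, 5], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "bloating": {"items": [3], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "digestive_symptoms": {"items": [6, 7], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "taste": {"items": [8], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "indigestion": {"items": [9], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "flatulence": {"items": [10], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "weight_loss": {"items": [11], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "weakness": {"items": [12], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "dry_mouth": {"items": [13], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "hepatic_symptoms": {"items": [14, 15], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "altered_bowel_habit": {"items": [16, 17], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "body_image": {"items": [18, 19], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "side_effects": {"items": [20], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "future_worries": {"items": [21], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "planning_activities": {"items": [22], "range": 3, "type": "symptom", "direction": "higher_is_worse"},
    "healthcare_satisfaction": {"items": [23, 24], "range": 3, "type": "symptom", "direction": "higher_is_better"},
    "sexuality": {"items": [25, 26], "range": 3, "type": "symptom", "direction": "higher_is_worse"}
  }
}
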