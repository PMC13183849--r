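{
  "anxious":     {"disorder": "anxiety",    "weight": 40},
  "worry":       {"disorder": "anxiety",    "weight": 30},
  "worrying":    {"disorder": "anxiety",    "weight": 30},
  "nervous":     {"disorder": "anxiety",    "weight": 35},
  "panic":       {"disorder": "anxiety",    "weight": 50},
  "restless":    {"disorder": "anxiety",    "weight": 25},
  "afraid":      {"disorder": "anxiety",    "weight": 35},
  "dread":       {"disorder": "anxiety",    "weight": 45},
  "edge":        {"disorder": "anxiety",    "weight": 20},
  "sad":         {"disorder": "depression", "weight": 35},
  "hopeless":    {"disorder": "depression", "weight": 55},
  "empty":       {"disorder": "depression", "weight": 40},
  "worthless":   {"disorder": "depression", "weight": 55},
  "tired":       {"disorder": "depression", "weight": 20},
  "sleep":       {"disorder": "depression", "weight": 15},
  "appetite":    {"disorder": "depression", "weight": 20},
  "down":        {"disorder": "depression", "weight": 30},
  "lonely":      {"disorder": "depression", "weight": 35},
  "overwhelmed": {"disorder": "stress",     "weight": 45},
  "pressure":    {"disorder": "stress",     "weight": 35},
  "stressed":    {"disorder": "stress",     "weight": 45},
  "deadline":    {"disorder": "stress",     "weight": 25},
  "overloaded":  {"disorder": "stress",     "weight": 40},
  "irritable":   {"disorder": "stress",     "weight": 25},
  "cope":        {"disorder": "stress",     "weight": 30},
  "tense":       {"disorder": "stress",     "weight": 35}
}
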