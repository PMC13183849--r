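{
  "anxiety": {
    "name": "anxiety",
    "scale": "GAD-7",
    "item_count": 7,
    "likert_min": 0,
    "likert_max": 3,
    "reverse_items": [],
    "severity_bands": [
      {"lower": 0,  "upper": 4,  "label": "Minimal anxiety"},
      {"lower": 5,  "upper": 9,  "label": "Mild anxiety"},
      {"lower": 10, "upper": 14, "label": "Moderate anxiety"},
      {"lower": 15, "upper": 21, "label": "Severe anxiety"}
    ],
    "diagnostic_cutoff": 10
  },
  "depression": {
    "name": "depression",
    "scale": "PHQ-9",
    "item_count": 9,
    "likert_min": 0,
    "likert_max": 3,
    "reverse_items": [],
    "severity_bands": [
      {"lower": 0,  "upper": 4,  "label": "Minimal depression"},
      {"lower": 5,  "upper": 9,  "label": "Mild depression"},
      {"lower": 10, "upper": 14, "label": "Moderate depression"},
      {"lower": 15, "upper": 19, "label": "Moderately severe depression"},
      {"lower": 20, "upper": 27, "label": "Severe depression"}
    ],
    "diagnostic_cutoff": 10
  },
  "stress": {
    "name": "stress",
    "scale": "PSS-10",
    "item_count": 10,
    "likert_min": 0,
    "likert_max": 4,
    "reverse_items": [4, 5, 7, 8],
    "severity_bands": [
      {"lower": 0,  "upper": 13, "label": "Low perceived stress"},
      {"lower": 14, "upper": 26, "label": "Moderate perceived stress"},
      {"lower": 27, "upper": 40, "label": "High perceived stress"}
    ],
    "diagnostic_cutoff": 27
  }
}
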