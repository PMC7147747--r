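# Named grade-scheme remappings. Each entry gives the ordered source grades
# (least severe first), the ordered target classes, an optional fallback
# class (default: first target class) and the source -> target map.
kaggle5to3:
  source: ["No DR", "Mild DR", "Moderate DR", "Severe DR", "Proliferative DR"]
  target: ["Healthy", "Non-referable DR", "Referable DR"]
  fallback: "Healthy"
  entries:
    "No DR": "Healthy"
    "Mild DR": "Non-referable DR"
    "Moderate DR": "Non-referable DR"
    "Severe DR": "Referable DR"
    "Proliferative DR": "Referable DR"
kaggle5to2:
  source: ["No DR", "Mild DR", "Moderate DR", "Severe DR", "Proliferative DR"]
  target: ["Healthy", "Diseased"]
  fallback: "Healthy"
  entries:
    "No DR": "Healthy"
    "Mild DR": "Diseased"
    "Moderate DR": "Diseased"
    "Severe DR": "Diseased"
    "Proliferative DR": "Diseased"
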