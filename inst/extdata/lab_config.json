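{
  "labs": [
    {"name": "bun", "label": "BUN", "regular": true, "lower_limit": 0.0, "lower_normal": 7.0, "upper_normal": 20.0, "upper_limit": 150.0, "severity_direction": 1, "two_sided": false},
    {"name": "potassium", "label": "Potassium", "regular": true, "lower_limit": 0.0, "lower_normal": 3.5, "upper_normal": 5.0, "upper_limit": 14.0, "severity_direction": 1, "two_sided": true},
    {"name": "platelets", "label": "Platelets", "regular": true, "lower_limit": 0.0, "lower_normal": 150.0, "upper_normal": 450.0, "upper_limit": 3000.0, "severity_direction": -1, "two_sided": false},
    {"name": "sodium", "label": "Sodium", "regular": true, "lower_limit": 85.0, "lower_normal": 135.0, "upper_normal": 145.0, "upper_limit": 200.0, "severity_direction": -1, "two_sided": true},
    {"name": "wbc", "label": "WBC", "regular": true, "lower_limit": 0.0, "lower_normal": 3.2, "upper_normal": 9.8, "upper_limit": 500.0, "severity_direction": 1, "two_sided": true},
    {"name": "ph_arterial", "label": "pH (arterial)", "regular": false, "lower_limit": 6.75, "lower_normal": 7.35, "upper_normal": 7.45, "upper_limit": 7.65, "severity_direction": -1, "two_sided": true},
    {"name": "ph_venous", "label": "pH (venous)", "regular": false, "lower_limit": 6.75, "lower_normal": 7.32, "upper_normal": 7.42, "upper_limit": 7.65, "severity_direction": -1, "two_sided": true},
    {"name": "pao2", "label": "PaO2", "regular": false, "lower_limit": 20.0, "lower_normal": 75.0, "upper_normal": 100.0, "upper_limit": 670.0, "severity_direction": -1, "two_sided": false},
    {"name": "paco2_arterial", "label": "PaCO2 (arterial)", "regular": false, "lower_limit": 5.0, "lower_normal": 35.0, "upper_normal": 45.0, "upper_limit": 200.0, "severity_direction": 1, "two_sided": true},
    {"name": "paco2_venous", "label": "PaCO2 (venous)", "regular": false, "lower_limit": 5.0, "lower_normal": 39.0, "upper_normal": 55.0, "upper_limit": 200.0, "severity_direction": 1, "two_sided": true},
    {"name": "lactate", "label": "Lactate", "regular": false, "lower_limit": 0.0, "lower_normal": 0.5, "upper_normal": 2.2, "upper_limit": 20.0, "severity_direction": 1, "two_sided": false},
    {"name": "troponin", "label": "Troponin", "regular": false, "lower_limit": 0.0, "lower_normal": 0.0, "upper_normal": 0.1, "upper_limit": 40.0, "severity_direction": 1, "two_sided": false}
  ]
}
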