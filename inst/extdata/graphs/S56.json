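{
  "schema": "llrsim-process-graph/1",
  "category": "S56",
  "nodes": [
    {"id": "trocar1", "label": "Trocar 1", "module": "P07M01", "p": 1},
    {"id": "insufflation", "label": "Insufflation", "module": "P07M02", "p": 1},
    {"id": "trocar2", "label": "Trocar 2", "module": "P07M01", "p": 1},
    {"id": "trocar3", "label": "Trocar 3", "module": "P07M01", "p": 1},
    {"id": "trocar4", "label": "Trocar 4", "module": "P07M01", "p": 0.6},
    {"id": "fat_adhesion", "label": "Fat/adhesion dissection", "module": "P08aM01", "p": 0.2},
    {"id": "mobilization_liver", "label": "Mobilization liver", "module": "P08aM02", "p": 0.4},
    {"id": "imaging", "label": "Imaging (US)", "module": "P05M02", "p": 1},
    {"id": "planning", "label": "Planning", "module": "P06M01", "p": 1},
    {"id": "marking", "label": "Region marking", "module": "P10M01", "p": 1},
    {"id": "resection", "label": "Resection", "module": "P10M02", "p": 1},
    {"id": "duct_isolation", "label": "Supply-duct isolation", "module": "P08aM03", "p": 0.6},
    {"id": "duct_occlusion", "label": "Permanent occlusion", "module": "P08aM05", "p": 0.6},
    {"id": "duct_division", "label": "Supply-duct division", "module": "P08aM06", "p": 0.6},
    {"id": "leakage_cleanup", "label": "Leakage clean-up", "module": "P13M04", "p": 1},
    {"id": "leak_testing", "label": "Leak testing", "module": "P13M05", "p": 0.4},
    {"id": "leak_closure", "label": "Leak closure", "module": "P13M06", "p": 1},
    {"id": "package", "label": "Package", "module": "P13M02", "p": 1},
    {"id": "removal", "label": "Removal", "module": "P13M03", "p": 1},
    {"id": "desufflation", "label": "Desufflation", "module": "P13M08", "p": 1},
    {"id": "incision_closing", "label": "Incision closing", "module": "P13M09", "p": 1}
  ],
  "edges": [
    ["start", "trocar1"],
    ["trocar1", "insufflation"],
    ["insufflation", "trocar2"],
    ["trocar2", "trocar3"],
    ["trocar3", "q_trocar4"],
    ["q_trocar4", "trocar4"],
    ["q_trocar4", "fat_adhesion"],
    ["trocar4", "fat_adhesion"],
    ["fat_adhesion", "mobilization_liver"],
    ["mobilization_liver", "marking"],
    ["marking", "resection"],
    ["resection", "q_ducts"],
    ["q_ducts", "duct_isolation"],
    ["q_ducts", "leakage_cleanup"],
    ["duct_isolation", "duct_occlusion"],
    ["duct_occlusion", "duct_division"],
    ["duct_division", "q_more_ducts"],
    ["q_more_ducts", "duct_isolation"],
    ["q_more_ducts", "resection"],
    ["leakage_cleanup", "leak_testing"],
    ["leak_testing", "leak_closure"],
    ["leak_closure", "package"],
    ["package", "removal"],
    ["removal", "desufflation"],
    ["desufflation", "incision_closing"],
    ["incision_closing", "end"]
  ],
  "free_order_groups": [
    ["fat_adhesion", "mobilization_liver"],
    ["leakage_cleanup", "leak_testing", "leak_closure"]
  ],
  "insertable": ["imaging", "planning"],
  "questions": [
    {"id": "q_trocar4", "at": "trocar3", "dynamic": false, "module": null,
     "outcomes": {"place": 0.6, "skip": 0.4}},
    {"id": "q_ducts", "at": "resection", "dynamic": false, "module": null,
     "outcomes": {"divide": 0.6, "continue": 0.4}},
    {"id": "q_more_ducts", "at": "duct_division", "dynamic": true,
     "module": "P08aM03", "outcomes": null}
  ],
  "precedence": [
    ["P07M01", "P10M01", "P10M02"],
    ["P07M02", "P10M02"]
  ],
  "most_probable_path": [
    "trocar1", "insufflation", "trocar2", "trocar3", "imaging", "planning",
    "marking", "resection", "leakage_cleanup", "leak_closure", "package",
    "removal", "desufflation", "incision_closing"
  ]
}
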