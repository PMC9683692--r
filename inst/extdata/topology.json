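{
  "name": "reduced closed-loop circulation",
  "compartments": [
    {"name": "RA",   "kind": "chamber",  "label": "right atrium"},
    {"name": "RV",   "kind": "chamber",  "label": "right ventricle"},
    {"name": "LA",   "kind": "chamber",  "label": "left atrium"},
    {"name": "LV",   "kind": "chamber",  "label": "left ventricle"},
    {"name": "trv",  "kind": "valve",    "label": "tricuspid valve"},
    {"name": "puv",  "kind": "valve",    "label": "pulmonary valve"},
    {"name": "miv",  "kind": "valve",    "label": "mitral valve"},
    {"name": "aov",  "kind": "valve",    "label": "aortic valve"},
    {"name": "par",  "kind": "vessel",   "label": "pulmonary artery"},
    {"name": "pvn",  "kind": "vessel",   "label": "pulmonary vein"},
    {"name": "AO",   "kind": "vessel",   "label": "aortic root and systemic arteries"},
    {"name": "CER",  "kind": "vessel",   "label": "carotid/cerebral arteries (middle cerebral pressure site)"},
    {"name": "LE_T", "kind": "terminal", "label": "leg terminal bed"},
    {"name": "BR_T", "kind": "terminal", "label": "brachial terminal bed"},
    {"name": "AC_T", "kind": "terminal", "label": "anterior cerebral terminal bed"},
    {"name": "EC_T", "kind": "terminal", "label": "external carotid terminal bed"},
    {"name": "MC_T", "kind": "terminal", "label": "middle cerebral terminal bed"},
    {"name": "PC_T", "kind": "terminal", "label": "posterior cerebral terminal bed"},
    {"name": "TR_T", "kind": "terminal", "label": "trunk terminal bed"},
    {"name": "vub",  "kind": "vein",     "label": "venous upper body"},
    {"name": "svc",  "kind": "vein",     "label": "superior vena cava"},
    {"name": "vlb",  "kind": "vein",     "label": "venous lower body"},
    {"name": "ivc",  "kind": "vein",     "label": "inferior vena cava"}
  ],
  "connections": [
    {"from": "RA",   "to": "trv"},
    {"from": "trv",  "to": "RV"},
    {"from": "RV",   "to": "puv"},
    {"from": "puv",  "to": "par"},
    {"from": "par",  "to": "pvn"},
    {"from": "pvn",  "to": "LA"},
    {"from": "LA",   "to": "miv"},
    {"from": "miv",  "to": "LV"},
    {"from": "LV",   "to": "aov"},
    {"from": "aov",  "to": "AO"},
    {"from": "AO",   "to": "BR_T"},
    {"from": "AO",   "to": "LE_T"},
    {"from": "AO",   "to": "TR_T"},
    {"from": "AO",   "to": "CER"},
    {"from": "CER",  "to": "AC_T"},
    {"from": "CER",  "to": "EC_T"},
    {"from": "CER",  "to": "MC_T"},
    {"from": "CER",  "to": "PC_T"},
    {"from": "BR_T", "to": "vub"},
    {"from": "AC_T", "to": "vub"},
    {"from": "EC_T", "to": "vub"},
    {"from": "MC_T", "to": "vub"},
    {"from": "PC_T", "to": "vub"},
    {"from": "LE_T", "to": "vlb"},
    {"from": "TR_T", "to": "vlb"},
    {"from": "vub",  "to": "svc"},
    {"from": "svc",  "to": "RA"},
    {"from": "vlb",  "to": "ivc"},
    {"from": "ivc",  "to": "RA"}
  ]
}
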