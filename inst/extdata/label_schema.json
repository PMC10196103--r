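{
  "name": "sellar_region_7class",
  "orientation": "axis1: left->right (sagittal stack); axis2: posterior->anterior; axis3: inferior->superior",
  "labels": [
    {"value": 0, "name": "background", "description": "non-labeled component"},
    {"value": 1, "name": "tumor", "description": "all tumor components including enhanced cyst walls and heterogeneous cysts"},
    {"value": 2, "name": "pituitary", "description": "pituitary gland and pituitary stalk (one class)"},
    {"value": 3, "name": "sphenoid_sinus", "description": "air space of the sphenoid sinus plus the bony wall / dura around the pituitary fossa"},
    {"value": 4, "name": "brain", "description": "cerebrum, cerebellum and brainstem"},
    {"value": 5, "name": "suprasellar_cistern", "description": "suprasellar and interpeduncular cisterns; may be absent under tumor compression"},
    {"value": 6, "name": "ventricle", "description": "lateral ventricles"}
  ]
}
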