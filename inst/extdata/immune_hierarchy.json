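{
  "children": {
    "T": ["CD4_T", "CD8_T"],
    "B": ["naive_B", "memory_B", "plasma"],
    "monocyte": ["classical_monocyte", "non_classical_monocyte"],
    "macrophage": ["M1_macrophage", "M2_macrophage"],
    "DC": ["pDC", "cDC"],
    "NK": ["NK_bright", "NK_dim"],
    "ILC": ["ILC1", "ILC2", "ILC3"],
    "mast": [],
    "neutrophil": [],
    "CD4_T": ["CD4_naive", "CD4_central_memory", "CD4_effector_memory", "Treg", "Tfh", "Th1", "Th2", "Th17"],
    "CD8_T": ["CD8_naive", "CD8_central_memory", "CD8_effector_memory", "CD8_cytotoxic", "CD8_exhausted"]
  },
  "prescreen": {
    "immune": "immune",
    "non_immune": "non_immune"
  }
}
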