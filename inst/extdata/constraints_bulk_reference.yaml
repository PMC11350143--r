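# Illustrative hierarchical proportion-constraint model, styled on
# compartment estimates from bulk pan-cancer deconvolution surveys.
# Synthetic values: each node's min/max is relative to its parent
# (mean +/- ~2 SD semantics), not derived from any deposited dataset.
root:
  min: 1.0
  max: 1.0
  children:
    cancer: {min: 0.15, max: 0.75}
    stroma:
      min: 0.05
      max: 0.35
      children:
        endothelial: {min: 0.30, max: 0.70}
        fibroblast: {min: 0.30, max: 0.70}
    leukocyte:
      min: 0.10
      max: 0.65
      children:
        memory_CD4_T: {min: 0.05, max: 0.30}
        naive_CD4_T: {min: 0.05, max: 0.30}
        Treg: {min: 0.02, max: 0.12}
        CD8_T:
          min: 0.08
          max: 0.40
          children:
            memory_CD8_T: {min: 0.30, max: 0.80}
            naive_CD8_T: {min: 0.20, max: 0.70}
        B:
          min: 0.03
          max: 0.25
          children:
            memory_B: {min: 0.20, max: 0.60}
            naive_B: {min: 0.40, max: 0.80}
        NK: {min: 0.02, max: 0.20}
        neutrophil: {min: 0.02, max: 0.30}
        dendritic: {min: 0.01, max: 0.08}
        monocyte: {min: 0.05, max: 0.30}
        macrophage: {min: 0.02, max: 0.25}
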