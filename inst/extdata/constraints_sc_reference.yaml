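# Illustrative hierarchical proportion-constraint model, styled on cell
# compositions reported by single-cell tumor atlases. Synthetic values:
# each node's min/max is relative to its parent; some minima sit below the
# 0.01 floor on purpose (the floor is applied when models are combined).
root:
  min: 1.0
  max: 1.0
  children:
    cancer: {min: 0.25, max: 0.85}
    stroma:
      min: 0.02
      max: 0.25
      children:
        endothelial: {min: 0.25, max: 0.65}
        fibroblast: {min: 0.35, max: 0.75}
    leukocyte:
      min: 0.12
      max: 0.70
      children:
        memory_CD4_T: {min: 0.04, max: 0.35}
        naive_CD4_T: {min: 0.03, max: 0.25}
        Treg: {min: 0.015, max: 0.15}
        CD8_T:
          min: 0.06
          max: 0.45
          children:
            memory_CD8_T: {min: 0.35, max: 0.85}
            naive_CD8_T: {min: 0.15, max: 0.65}
        B:
          min: 0.02
          max: 0.30
          children:
            memory_B: {min: 0.15, max: 0.55}
            naive_B: {min: 0.45, max: 0.85}
        NK: {min: 0.015, max: 0.18}
        neutrophil: {min: 0.005, max: 0.20}
        dendritic: {min: 0.005, max: 0.10}
        monocyte: {min: 0.04, max: 0.35}
        macrophage: {min: 0.03, max: 0.30}
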