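# Two-composite model (three indicators per block) together with the
# benchmark population parameters of model 1: intra-block correlations 0.5,
# composite correlation 0.3, weights (0.6, 0.2, 0.4) and (0.4, 0.2, 0.6).
blocks:
  c1: [x11, x12, x13]
  c2: [x21, x22, x23]
population:
  weights:
    c1: [0.6, 0.2, 0.4]
    c2: [0.4, 0.2, 0.6]
  composite_corr:
    - [1.0, 0.3]
    - [0.3, 1.0]
  intra_block_corr:
    c1:
      - [1.0, 0.5, 0.5]
      - [0.5, 1.0, 0.5]
      - [0.5, 0.5, 1.0]
    c2:
      - [1.0, 0.5, 0.5]
      - [0.5, 1.0, 0.5]
      - [0.5, 0.5, 1.0]
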