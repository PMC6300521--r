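# Three-composite benchmark model (population model 4). The intra-block
# correlation matrices are a SYNTHETIC RECONSTRUCTION, not canonical: they
# are pinned down by unit composite variance in every block, an
# equicorrelated first block (0.5), and a model-implied (x13, x21)
# correlation of exactly 0.084. 1/11 = 0.09090909..., 0.34/1.3 = 0.26153846...
blocks:
  c1: [x11, x12, x13]
  c2: [x21, x22, x23]
  c3: [x31, x32, x33]
population:
  weights:
    c1: [0.6, 0.4, 0.2]
    c2: [0.3, 0.5, 0.6]
    c3: [0.4, 0.5, 0.5]
  composite_corr:
    - [1.0, 0.3, 0.5]
    - [0.3, 1.0, 0.4]
    - [0.5, 0.4, 1.0]
  intra_block_corr:
    c1:
      - [1.0, 0.5, 0.5]
      - [0.5, 1.0, 0.5]
      - [0.5, 0.5, 1.0]
    c2:
      - [1.0, 0.0909090909090909, 0.0909090909090909]
      - [0.0909090909090909, 1.0, 0.4]
      - [0.0909090909090909, 0.4, 1.0]
    c3:
      - [1.0, 0.2615384615384615, 0.2615384615384615]
      - [0.2615384615384615, 1.0, 0.2615384615384615]
      - [0.2615384615384615, 0.2615384615384615, 1.0]
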