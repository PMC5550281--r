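# Demo run: a 1/20-scale synthetic alpha lobe (48 KCs, full extrinsic
# census) analysed with the default parameters (300 nm convergence
# radius, min expected count 0.5, fit classes 0.05/0.003).
generator:
  n_kc:
    KC-ab-s: 24
    KC-ab-c-o: 7
    KC-ab-c-i: 13
    KC-ab-p: 4
  seed: 101
radius: 300
coverage_radii_nm:
  from: 0
  to: 3000
  by: 100
min_expected: 0.5
df_convention: bins
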