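# Packaged 16-point breast DWI protocol: b-values (s/mm^2) with the
# per-b excitation counts (NEX) of the clinical acquisition.
b:   [0, 10, 20, 30, 50, 70, 100, 150, 200, 400, 800, 1200, 1500, 2000, 2500, 3000]
nex: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 3, 6, 7, 7]
model:
  form: product     # hindered term exp(-(b*D_H)^alpha_H)
  d_ui: 3.0         # um^2/ms, fixed free-water diffusivity
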