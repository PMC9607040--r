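# D_wall against alpha for several compressibility values; caption: R = 10, lambda1 = 1.
alpha: 0.5
reynolds: 10
chi: 0.3
lambda1: 1.0
sweep_param: chi
sweep_values: [0.001, 0.2, 0.4, 0.6]
observable: d_wall
grid_from: 0.01
grid_to: 2.0
grid_n: 200
variants: [linear, ucm]
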