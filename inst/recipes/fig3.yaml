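# G(y) for several compressibility values; caption: R = 100, alpha = 0.5, lambda1 = 0.5.
alpha: 0.5
reynolds: 100
chi: 0.3
lambda1: 0.5
sweep_param: chi
sweep_values: [0.001, 0.2, 0.4, 0.6]
observable: G
grid_from: 0.0
grid_to: 1.0
grid_n: 101
variants: [linear, ucm]
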