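# Mean axial velocity profiles for several compressibility values (panel b);
# caption: R = 1, alpha = 0.4, lambda1 = 0.5.
alpha: 0.4
reynolds: 1
chi: 0.3
lambda1: 0.5
epsilon: 0.1
sweep_param: chi
sweep_values: [0.001, 0.2, 0.4, 0.6]
observable: mean_u
grid_from: -1.0
grid_to: 1.0
grid_n: 201
variants: [linear, ucm]
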