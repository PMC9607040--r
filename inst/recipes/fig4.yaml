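# D_wall against alpha for several relaxation times; caption: R = 50, chi = 0.001.
alpha: 0.5
reynolds: 50
chi: 0.001
lambda1: 0.5
sweep_param: lambda1
sweep_values: [0.0, 0.5, 1.0, 2.0]
observable: d_wall
grid_from: 0.01
grid_to: 2.0
grid_n: 200
variants: [linear, ucm]
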