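# G(y) for several relaxation times; caption: R = 10, chi = 0.3, alpha = 0.5.
# The swept lambda1 set is not printed in the caption; documented default below.
alpha: 0.5
reynolds: 10
chi: 0.3
lambda1: 0.5
sweep_param: lambda1
sweep_values: [0.0, 0.5, 1.0, 2.0]
observable: G
grid_from: 0.0
grid_to: 1.0
grid_n: 101
variants: [linear, ucm]
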