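# Net flow rate against alpha for several relaxation times;
# caption: R = 10^4, chi = 0.3, amplitude ratio 0.5.
alpha: 0.5
reynolds: 10000
chi: 0.3
lambda1: 1.0
epsilon: 0.5
sweep_param: lambda1
sweep_values: [0.0, 1.0, 5.0]
observable: Q
grid_from: 0.01
grid_to: 2.0
grid_n: 200
variants: [linear, ucm]
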