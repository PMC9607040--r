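# Mean axial velocity profiles for several relaxation times;
# caption: R = 10, alpha = 0.5, chi = 0.05.  The top lambda1 value reaches
# the near-wall flow-reversal regime visible in the convected-model panel.
alpha: 0.5
reynolds: 10
chi: 0.05
lambda1: 0.5
epsilon: 0.1
sweep_param: lambda1
sweep_values: [0.0, 1.0, 2.0, 5.0]
observable: mean_u
grid_from: -1.0
grid_to: 1.0
grid_n: 201
variants: [linear, ucm]
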