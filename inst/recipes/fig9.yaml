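# Net flow rate against alpha at very large relaxation time;
# caption: lambda1 = 10000, R = 10^4, chi = 0.6, amplitude ratio 0.5.
# Fine alpha grid: Q(alpha) oscillates on a scale ~ 2*pi/sqrt(lambda1*R).
alpha: 0.5
reynolds: 10000
chi: 0.6
lambda1: 10000
epsilon: 0.5
sweep_param: none
observable: Q
grid_from: 0.002
grid_to: 0.2
grid_n: 400
variants: [linear, ucm]
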