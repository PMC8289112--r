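# Asymmetric parameter set (plague-locust-like): solitarisation an order of
# magnitude slower than gregarisation, dimensionless units.
D: 2.041
gamma: 294.44
R_s: 878.1
r_s: 1.0
R_g: 775.6
r_g: 0.2857
A_g: 1658.6
k: 0.1
delta: 1.778
kappa: 0.18
transition_form: divide
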