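# Symmetric gregarisation/solitarisation parameter set (desert-locust-like):
# equal maximal transition rates, dimensionless units.
D: 2.041
gamma: 431.87
R_s: 1063.5
r_s: 1.0
R_g: 940.5
r_g: 0.2857
A_g: 2008.7
k: 0.681
delta: 1.0
kappa: 0.09
transition_form: divide
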