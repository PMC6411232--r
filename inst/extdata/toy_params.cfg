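# exactly solvable overflow-metabolism network: literature-calibrated defaults
V_g = 0.5
R = 0.45
e = 1
y = 348
tau = 0.0022
c_g = 15
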