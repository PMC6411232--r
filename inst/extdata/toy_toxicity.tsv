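metabolite_id	K_inhib_mM	tau_per_h_per_mM
lac	8	0.0022
nh4	1.05	
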