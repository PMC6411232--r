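metabolite_id	c_mM	V_max
glc	15	0.5
lac	0	0
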