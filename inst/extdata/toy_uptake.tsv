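metabolite_id	V_max
S	0.5
W	0
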