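reaction_id	alpha_fwd	alpha_rev
gly	0	0
resp	2.2222222222222223	0
sec	0	0
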