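metabolite_id	rate
E	1.0625
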