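class	cf	cf_sd
cA34	0.17	0.05
cA5	0.62	0.7
cA6	0.12	0.3
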