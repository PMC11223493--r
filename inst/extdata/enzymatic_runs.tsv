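complex	r_e	r_e_sd	frac_cA34	frac_cA34_sd	frac_cA5	frac_cA5_sd	frac_cA6	frac_cA6_sd	dilution	complex_conc_uM
type_III-A	0.47	0.19	89	16	8	3	3	1	21	0.0625
type_III-B	1.17	0.11	81	14	12	5	7	3	27.6	0.0625
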