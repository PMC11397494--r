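id	class	width	pi
E1	cne	100	0.00821429
E2	intergenic	120	0.00857143
E4	exon	100	0.00250000
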