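chrI	1000	1100	E1	cne
chrI	1200	1320	E2	intergenic
chrI	1400	1440	E3	cne
chrI	1500	1600	E4	exon
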