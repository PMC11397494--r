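id	gene_id	distance
CNE00001	gA	0
CNE00002	gB	20
CNE00003	gC	0
CNE00004	gC	0
CNE00005	gD	0
CNE00006	gD	-130
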