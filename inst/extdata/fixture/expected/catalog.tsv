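id	chrom	start	end	status_C_briggsae	status_C_elegans	status_C_inopinata
CNE00001	chrI	100	120	kept	kept	dropped_length_ratio
CNE00002	chrI	400	460	kept	kept	kept
CNE00003	chrI	700	720	dropped_redundant	kept	kept
CNE00004	chrI	730	760	kept	kept	kept
CNE00005	chrI	770	790	kept	kept	kept
CNE00006	chrI	900	911	unaligned	kept	kept
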