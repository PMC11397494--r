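chrI	100	140	S1
chrI	300	308	S2
chrI	400	460	S3
chrI	500	540	S4
chrI	700	790	S5
chrI	900	911	S6
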