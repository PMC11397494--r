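classA	classB	n	nNeighbor	oddsRatio	p	q
XX-biased	XX-biased	2	0	0.428571	1.00000000	1.00000000
XX-biased	XO-biased	0	0	2.71429	1.00000000	1.00000000
XX-biased	Non	2	0	0.428571	1.00000000	1.00000000
XO-biased	XX-biased	2	1	4	0.45454545	1.00000000
XO-biased	XO-biased	2	0	0.428571	1.00000000	1.00000000
XO-biased	Non	0	0	2.71429	1.00000000	1.00000000
Non	XX-biased	2	2	31.6667	0.04545455	0.40909091
Non	XO-biased	0	0	2.71429	1.00000000	1.00000000
Non	Non	2	0	0.428571	1.00000000	1.00000000
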