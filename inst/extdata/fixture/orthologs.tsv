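geneA	geneB
g1	h1
g2	h2
g3	h3
g4	h4
g5	h5
g6	h6
g7	h7
g8	h8
g9	h9
g10	h10
g11	h11
g12	h12
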