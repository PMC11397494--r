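gene	class
g1	Non
g2	Non
g3	Non
g4	Non
g5	XX-biased
g6	XX-biased
g7	XX-biased
g8	XX-biased
g9	XO-biased
g10	XO-biased
g11	XO-biased
g12	XO-biased
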