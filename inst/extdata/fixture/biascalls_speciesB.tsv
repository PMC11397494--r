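gene	class
h1	XX-biased
h2	XX-biased
h3	Non
h4	Non
h5	XX-biased
h6	XX-biased
h7	Non
h8	Non
h9	XO-biased
h10	XO-biased
h11	XX-biased
h12	XX-biased
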