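##maf version=1

a score=0.0
s C_niphades.chrI 80 70 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC-------------------------ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
s C_elegans.chrI 80 70 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC-------------------------ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
s C_briggsae.chrI 80 70 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC-------------------------ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
s C_inopinata.chrI 80 95 + 2000 ACGTACGTACGTACGTACGTACGTACGTACACGTACGTACGTACGTACGTACGTAACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT

a score=0.0
s C_niphades.chrI 295 30 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC
s C_elegans.chrI 295 30 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC
s C_briggsae.chrI 295 30 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC
s C_inopinata.chrI 295 30 + 2000 ACGTACGTACGTACGTACGTACGTACGTAC

a score=0.0
s C_niphades.chrI 395 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_elegans.chrI 395 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_briggsae.chrI 395 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_inopinata.chrI 395 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG

a score=0.0
s C_niphades.chrI 695 15 + 2000 ACGTACGTACGTACG
s C_elegans.chrI 695 15 + 2000 ACGTACGTACGTACG
s C_briggsae.chrI 695 15 + 2000 ACGTACGTACGTACG
s C_inopinata.chrI 695 15 + 2000 ACGTACGTACGTACG

a score=0.0
s C_niphades.chrI 710 15 + 2000 ACGTACGTACGTACG
s C_elegans.chrI 710 15 + 2000 ACGTACGTACGTACG
s C_briggsae.chrI 1500 15 + 2000 ACGTACGTACGTACG
s C_inopinata.chrI 710 15 + 2000 ACGTACGTACGTACG

a score=0.0
s C_niphades.chrI 725 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_elegans.chrI 725 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_briggsae.chrI 725 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG
s C_inopinata.chrI 725 75 + 2000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACG

a score=0.0
s C_niphades.chrI 895 20 + 2000 ACGTACGTACGTACGTACGT
s C_elegans.chrI 895 20 + 2000 ACGTACGTACGTACGTACGT
s C_inopinata.chrI 895 20 + 2000 ACGTACGTACGTACGTACGT
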