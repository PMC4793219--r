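gene	n_sites_up	n_sites_down
MDM2	22	0
MDM4	24	15
TP53	0	2
ATM	20	0
VHL	47	0
CASP8	12	2
IDH2	0	11
BRCA2	3	0
ERCC4	2	0
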