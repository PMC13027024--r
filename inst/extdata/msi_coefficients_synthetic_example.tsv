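# SYNTHETIC example of the hypermutator-signature coefficient file format.
# These weights are placeholders for format documentation and testing only;
# they are NOT the published signature coefficients, which users must supply.
gene	weight
EPM2AIP1	-1
TTC30A	-1
SMAP1	-1
RNLS	-1
WNT11	-1
SFXN1	-1
SREBF1	1
TYMS	1
EIF5AL1	1
WDR76	1
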