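# The 22 published network genes enriched in the epilepsy co-expression network.
CACNA1C
CACNB2
CACNB4
CHRNB2
DNM1
EEF1A2
GABRA1
GABRA3
GABRA4
GABRB2
GABRB3
GABRG2
GRIN1
KCNA2
KCNC1
KCNQ3
SCN1A
SCN4B
SCN8A
SOD1
STXBP1
SV2A
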