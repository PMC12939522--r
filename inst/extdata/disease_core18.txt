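TNF
IL1B
IL6
IL17A
IL23R
CRP
IL1RN
MMP3
NOD2
HLA-B
ERAP1
ZNF354A
TAP1
TAP2
FRG2C
USP50
LIN54
ERAP2
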