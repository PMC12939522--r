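FN1
AKT1
IL6
TP53
EGFR
SRC
CTNNB1
STAT3
MMP9
TGFB1
INS
IL1B
NFKB1
MYC
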