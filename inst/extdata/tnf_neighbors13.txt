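TNF
HLA-B
IL10
PTPN11
AKT1
NTRK1
CTNNB1
BDNF
CTLA4
MYC
CD36
ACTB
NOTCH1
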