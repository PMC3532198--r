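# SYNTHETIC stand-in for a pan-cancer exclusion list (genes reported as
# commonly over-expressed across many cancer types). The published list of
# 18 such genes is not deposited; this file exists to exercise the gene-list
# reader and the subtractive filter, not as curated biology.
MKI67
TOP2A
CCNB1
BIRC5
PCNA
AURKA
PLK1
CDK1
MCM2
RRM2
TYMS
FOXM1
EZH2
CENPF
KIF11
TPX2
UBE2C
MYBL2
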