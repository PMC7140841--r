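# Default DNA-repair gene panel.
# The 17 genes in which damaging case variants were observed, extended with
# canonical DNA-repair genes routinely screened by germline cancer panels.
# The published analysis used a 175-gene panel that is not reproduced in
# print; supply your own panel file for faithful reuse on real data.
ATM
BRCA1
CHEK2
ERCC3
FAN1
FANCM
HLTF
MRE11A
MUTYH
NEIL1
NTHL1
POLG
POLL
RAD18
RECQL
RECQL5
TP53
# extension list
ATR
BLM
BRCA2
BRIP1
ERCC2
ERCC4
ERCC5
FANCA
FANCC
MLH1
MSH2
MSH6
NBN
PALB2
PMS2
RAD51C
RAD51D
WRN
XRCC2
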