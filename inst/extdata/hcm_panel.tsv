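gene	chromosome	core
ACTA1	1	FALSE
ACTC1	15	TRUE
ACTN2	1	FALSE
ANKRD1	10	FALSE
BRAF	7	FALSE
CALR3	19	FALSE
CASQ2	1	FALSE
CAV3	3	FALSE
COX15	10	FALSE
CRYAB	11	FALSE
CSRP3	11	FALSE
DES	2	FALSE
FHL1	X	FALSE
FXN	9	FALSE
GAA	17	FALSE
GLA	X	FALSE
JPH2	20	FALSE
KLF10	8	FALSE
LAMP2	X	FALSE
LDB3	10	FALSE
MAP2K1	15	FALSE
MAP2K2	19	FALSE
MYBPC3	11	TRUE
MYH6	14	FALSE
MYH7	14	TRUE
MYL2	12	TRUE
MYL3	3	TRUE
MYLK2	20	FALSE
MYO6	6	FALSE
MYOZ2	4	FALSE
MYPN	10	FALSE
NEXN	1	FALSE
PDLIM3	4	FALSE
PLN	6	FALSE
PRKAG2	7	FALSE
PTPN11	12	FALSE
RAF1	3	FALSE
SLC25A4	4	FALSE
SOS1	2	FALSE
TCAP	17	FALSE
TNNC1	3	FALSE
TNNI3	19	TRUE
TNNT2	1	TRUE
TPM1	15	TRUE
TRIM63	1	FALSE
TTN	2	FALSE
VCL	10	FALSE
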