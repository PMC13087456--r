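# Synthetic reconstruction of a minor-spliceosome candidate gene panel:
# the two catalytic snRNAs under study plus minor-spliceosome-specific and
# shared snRNP component genes, padded to 65 entries. This list is a
# user-replaceable stand-in, not the study's supplementary panel.
# Format: one gene per line, optional tab-separated class (coding/noncoding).
RNU6ATAC	noncoding
RNU4ATAC	noncoding
RNU11	noncoding
RNU12	noncoding
ZRSR2	coding
RNPC3	coding
PDCD7	coding
SNRNP25	coding
SNRNP35	coding
SNRNP48	coding
ZCRB1	coding
CENATAC	coding
ZMAT5	coding
SCNM1	coding
ARMC7	coding
SNRPB	coding
SNRPD1	coding
SNRPD2	coding
SNRPD3	coding
SNRPE	coding
SNRPF	coding
SNRPG	coding
LSM2	coding
LSM3	coding
LSM4	coding
LSM5	coding
LSM6	coding
LSM7	coding
LSM8	coding
PRPF8	coding
SNRNP200	coding
EFTUD2	coding
PRPF6	coding
PRPF19	coding
CDC5L	coding
PLRG1	coding
BCAS2	coding
CTNNBL1	coding
WBP11	coding
SF3B1	coding
SF3B2	coding
SF3B3	coding
SF3B4	coding
SF3B5	coding
PHF5A	coding
SNRNP40	coding
DDX23	coding
CD2BP2	coding
TXNL4A	coding
USP39	coding
SART1	coding
SART3	coding
PPIH	coding
PRPF3	coding
PRPF4	coding
PRPF31	coding
SNU13	coding
DHX15	coding
DHX8	coding
DDX41	coding
AQR	coding
RBM17	coding
SYF2	coding
ISY1	coding
XAB2	coding
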