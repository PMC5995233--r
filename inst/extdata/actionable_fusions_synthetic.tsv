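gene_a	gene_b
ALK	EML4
ROS1	SLC34A2
ROS1	CD74
RET	KIF5B
RET	CCDC6
RET	NCOA4
NTRK1	TPM3
NTRK1	LMNA
NTRK2	AGBL4
NTRK3	ETV6
FGFR2	BICC1
FGFR3	TACC3
FGFR1	TACC1
BRAF	KIAA1549
RAF1	SRGAP3
ABL1	BCR
PDGFRA	FIP1L1
PDGFRB	ETV6
EGFR	SEPT14
MET	KIF5B
ERG	TMPRSS2
ETV1	TMPRSS2
ESR1	CCDC170
ESR1	YAP1
NRG1	CD74
NRG1	SLC3A2
ALK	NPM1
ALK	TFG
ALK	KIF5B
ALK	STRN
BRD4	NUT
EWSR1	FLI1
EWSR1	ERG
PAX3	FOXO1
SS18	SSX1
TFE3	ASPSCR1
MAML2	CRTC1
PRKACA	DNAJB1
RELA	C11orf95
MYB	NFIB
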