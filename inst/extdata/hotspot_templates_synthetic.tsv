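gene	protein_change	ref	alt	classification
TP53	p.Gly112Asp	G	A	benign
TP53	p.Arg175His	G	A	pathogenic
TP53	p.Arg248Gln	G	A	pathogenic
TP53	p.Arg273His	G	A	pathogenic
KRAS	p.Gly12Asp	G	A	pathogenic
KRAS	p.Gly12Val	G	T	pathogenic
KRAS	p.Gly13Asp	G	A	pathogenic
NRAS	p.Gln61Lys	C	A	pathogenic
BRAF	p.Val600Glu	T	A	pathogenic
EGFR	p.Leu858Arg	T	G	pathogenic
EGFR	p.Thr790Met	C	T	pathogenic
EGFR	p.Glu746_Ala750del	GGAATTAAGAGAAGCA	G	pathogenic
PIK3CA	p.Glu545Lys	G	A	pathogenic
PIK3CA	p.His1047Arg	A	G	pathogenic
IDH1	p.Arg132His	G	A	pathogenic
IDH2	p.Arg140Gln	G	A	pathogenic
KIT	p.Asp816Val	A	T	pathogenic
ERBB2	p.Val777Leu	G	T	pathogenic
AKT1	p.Glu17Lys	G	A	pathogenic
CTNNB1	p.Ser45Phe	C	T	pathogenic
PTEN	p.Arg130Gln	G	A	pathogenic
APC	p.Thr1493Thr	C	T	benign
ATM	p.Asp1853Asn	G	A	VUS
MET	p.Thr1010Ile	C	T	VUS
FBXW7	p.Arg465Cys	C	T	pathogenic
SMAD4	p.Arg361His	G	A	pathogenic
STK11	p.Phe354Leu	C	A	VUS
VHL	p.Pro25Leu	C	T	benign
RB1	p.Arg455Ter	C	T	pathogenic
CDKN2A	p.Ala148Thr	G	A	benign
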