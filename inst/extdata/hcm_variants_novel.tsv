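gene	hgvs_c	hgvs_p	consequence	sift	provean	polyphen	mutation_taster	varsome_class	n_cases
ACTA1	c.848G>A	p.Ser283Asn	missense	D	N	B	DC	LP	1
ACTN2	c.411C>A	p.Ile137=	synonymous	T	N	NA	DC	LB	1
ACTN2	c.973G>T	p.Asp325Tyr	missense	D	D	PrD	DC	VUS	1
ANKRD1	c.566C>T	p.Ala189Val	missense	D	D	PoD	DC	VUS	1
CALR3	c.877G>T	p.Glu293Ter	stop_gained	D	NA	NA	DC	P	1
DES	c.462C>A	p.Leu154=	synonymous	T	N	NA	DC	LB	1
DES	c.1023T>G	p.Thr341=	synonymous	T	N	NA	DC	LP	1
DES	c.1095C>A	p.Asp365Glu	missense	T	N	B	DC	LP	1
DES	c.1104G>T	p.Ala368=	synonymous	T	N	NA	Pol	LB	1
GAA	c.352G>A	p.Gln118Lys	missense	T	N	B	Pol	VUS	1
JPH2	c.1683G>T	p.Ala561=	synonymous	T	N	NA	DC	LB	1
JPH2	c.1039G>T	p.Val347Phe	missense	D	D	PrD	DC	LB	1
KLF10	c.1060G>T	p.Ala354Ser	missense	T	N	B	Pol	VUS	1
LDB3	c.563G>A	p.Gly188Asp	missense	T	N	B	Pol	LB	1
LDB3	c.1103C>A	p.Pro368His	missense	T	N	NA	DC	LB	1
LDB3	c.1155C>A	p.Thr385=	synonymous	T	N	NA	Pol	LB	1
LDB3	c.1838C>A	p.Pro613Gln	missense	D	D	NA	DC	VUS	1
MYBPC3	c.2813C>T	p.Ala938Val	missense	D	N	PrD	DC	LP	1
MYBPC3	c.1965A>G	p.Ile655Met	missense	T	N	B	Pol	VUS	2
MYBPC3	c.1957_1962delGGCCGC	p.Gly653_Arg654del	inframe_indel	NA	D	NA	Pol	LP	2
MYBPC3	c.1252A>C	p.Lys418Gln	missense	T	N	B	DC	VUS	1
MYBPC3	c.1251C>T	p.Ala417=	synonymous	T	N	NA	DC	LB	1
MYBPC3	c.1247_1248insCCAG	p.Ala417GlnfsTer29	frameshift	NA	NA	NA	DC	P	1
MYBPC3	c.996G>T	p.Glu332Asp	missense	T	N	B	DC	VUS	1
MYH6	c.2571G>T	p.Glu857Asp	missense	T	N	PrD	DC	LB	1
MYH6	c.2346G>T	p.Arg782Ser	missense	D	D	B	DC	VUS	1
MYLK2	c.1431C>A	p.Ser477Arg	missense	D	D	PrD	DC	VUS	1
MYOZ2	c.236C>A	p.Ala79Glu	missense	T	N	PoD	DC	LB	1
NEXN	c.44C>A	p.Ser15Tyr	missense	D	N	PoD	DC	VUS	1
PRKAG2	c.1381C>T	p.Pro461Ser	missense	D	D	PrD	DC	VUS	1
SOS1	c.3434A>G	p.Asp1145Gly	missense	T	N	B	DC	VUS	1
TCAP	c.68C>A	p.Ala23Glu	missense	D	D	PoD	DC	VUS	1
TRIM63	c.697C>A	p.Gln233Lys	missense	T	N	B	Pol	LB	1
TTN	c.44530G>T	p.Ala14844Ser	missense	D	N	PrD	DC	VUS	1
TTN	c.30392G>T	p.Cys10131Phe	missense	T	D	B	DC	VUS	1
TTN	c.26928G>T	p.Leu8976=	synonymous	T	N	NA	DC	LB	1
TTN	c.25185G>T	p.Lys8395Asn	missense	D	D	PrD	DC	LB	1
TTN	c.22816+1G>T		splice_site	NA	NA	NA	DC	P	1
TTN	c.16783G>T	p.Val5595Leu	missense	T	N	B	Pol	LB	1
TTN	c.11927A>G	p.Lys3976Arg	missense	T	N	B	Pol	LB	1
TTN	c.11338G>T	p.Glu3780Ter	stop_gained	NA	NA	NA	DC	P	1
TTN	c.2518G>T	p.Ala840Ser	missense	D	N	B	DC	VUS	1
TTN	c.49G>T	p.Val17Leu	missense	T	N	B	DC	VUS	1
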