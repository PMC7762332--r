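gene	hgvs_c	hgvs_p	consequence	dbsnp_id	clinvar_id	clinvar_assertions	n_cases
ACTN2	c.2445C>T	p.Ile815=	synonymous	rs397516575	43929	LB	1
ANKRD1	c.197G>A	p.Arg66Gln	missense	rs150797476	45628	LB	1
BRAF	c.95_100dupGCGCCG	p.Gly32_Ala33dup	inframe_indel	rs397515331	41448	VUS	1
CAV3	c.39C>T	p.Ile13=	synonymous	rs200562715	179005	LB	1
CSRP3	c.208G>T	p.Gly70Trp	missense	rs777211110	520335	VUS	1
GAA	c.762G>A	p.Ser254=	synonymous	rs533960093	509666	LB	1
GAA	c.899C>A	p.Ala300Glu	missense	rs1032949450			1
KLF10	c.973G>A	p.Val325Ile	missense	rs760040811			1
LAMP2	c.37G>T	p.Gly13Trp	missense	rs12853266			1
LDB3	c.610G>A	p.Ala204Thr	missense	rs774976112	626705	LB,VUS	1
MAP2K1	c.315C>T	p.Pro105=	synonymous	rs144166521	44589	B	2
MYBPC3	c.3413G>C	p.Arg1138Pro	missense	rs187705120	42712	VUS	2
MYBPC3	c.3294G>A	p.Trp1098Ter	stop_gained	rs767039057	520341	P	1
MYBPC3	c.3262C>G	p.Pro1088Ala	missense	rs1263358939			1
MYBPC3	c.2882C>T	p.Pro961Leu	missense	rs373056282	42665	VUS	1
MYBPC3	c.2441_2443delAGA	p.Lys814del	inframe_indel	rs727504288	177700	VUS,LP	1
MYBPC3	c.1967C>T	p.Pro656Leu	missense	rs927421140			2
MYBPC3	c.1316G>A	p.Gly439Asp	missense	rs763045718	628463	VUS	1
MYBPC3	c.1127G>A	p.Ser376Asn	missense	rs1595846858			1
MYBPC3	c.772G>A	p.Glu258Lys	missense	rs397516074	42792	P	1
MYBPC3	c.152C>T	p.Ala51Val	missense	rs746738538			1
MYH6	c.2710G>T	p.Glu904Ter	stop_gained	rs759822161			1
MYH7	c.5736C>T	p.Ile1912=	synonymous	rs200728597	43086	B	1
MYH7	c.5203T>A	p.Ser1735Thr	missense	rs144066768	181272	VUS	1
MYH7	c.4377G>T	p.Lys1459Asn	missense	rs201307101	43012	LB	1
MYH7	c.4348G>A	p.Asp1450Asn	missense	rs397516211	43009	VUS	1
MYH7	c.4212G>T	p.Val1404=	synonymous	rs397516205	43000	LB	1
MYH7	c.2389G>A	p.Ala797Thr	missense	rs3218716	42901	LP,P	1
MYH7	c.1755C>T	p.Ile585=	synonymous	rs201860580	194465	LB,VUS	1
MYH7	c.1108G>A	p.Glu370Lys	missense		858379	VUS	1
MYH7	c.715G>A	p.Asp239Asn	missense	rs397516264	43100	LP,P	1
MYL2	c.374C>T	p.Thr125Met	missense	rs375667565	43473	VUS	1
MYO6	c.2322T>C	p.Pro774=	synonymous	rs947653207			1
MYPN	c.1012C>T	p.Arg338Cys	missense	rs140037748	201882	VUS	1
PDLIM3	c.334G>A	p.Gly112Arg	missense	rs777447396	967683	VUS	1
PRKAG2	c.147C>T	p.Asp49=	synonymous	rs761196275	696154	LB	1
SOS1	c.661C>G	p.Leu221Val	missense	rs1007628403			1
TNNI3	c.557G>A	p.Arg186Gln	missense	rs397516357	43395	LP,P	1
TNNT2	c.863G>A	p.Arg288His	missense	rs397516484	43674	VUS	1
TNNT2	c.774C>T	p.Phe258=	synonymous	rs397516481	43668	LB	1
TNNT2	c.430C>T	p.Arg144Trp	missense	rs45525839	127070	VUS	1
TNNT2	c.341C>T	p.Ala114Val	missense	rs727504245	177633	VUS,LP	1
TPM1	c.574G>A	p.Glu192Lys	missense	rs199476315	31882	P	1
TPM1	c.835C>T	p.Leu279=	synonymous	rs374434837	378751	LB	1
TTN	c.40423A>G	p.Lys13475Glu	missense	rs775980062			1
TTN	c.32736G>A	p.Pro10912=	synonymous	rs368838709			1
TTN	c.29079G>A	p.Ala9693=	synonymous	rs372997298	137775	B,LB,VUS	1
TTN	c.22386T>A	p.Asp7462Glu	missense	rs183482849	46699	B,VUS	1
TTN	c.20395C>T	p.Arg6799Trp	missense	rs751534449	809053	VUS	1
TTN	c.15856G>A	p.Gly5286Ser	missense	rs1409273228			1
TTN	c.11959A>G	p.Ile3987Val	missense	rs551387805	264496	LB,VUS	1
VCL	c.3186G>A	p.Gln1062=	synonymous	rs761534024	300798	LB,VUS	1
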