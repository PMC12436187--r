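case_id	variant_id	cdna_change	protein_change	coding_effect	protein_position	domain	sex	age_months	microcephaly	clinical_severity	css	age_at_mri_months	mri_severity	mri_ss	source
1	Q86Dfs*34	c.256dupC	p.Gln86AspfsTer34	frameshift	86	N_terminal	M	54	yes	moderate	1.06	11	severe	5	our_case
2	Q86Rfs*106	c.256delC	p.Gln86ArgfsTer106	frameshift	86	N_terminal	M	263	yes	severe	1.56	84	severe	6	our_case
3	E136X	c.406G>T	p.Glu136Ter	nonsense	136	N_terminal	M	33	yes	severe	1.44	7	moderate	4	literature_ref18
4	P182Q	c.545C>A	p.Pro182Gln	missense	182	FBD_CS	F	85	yes	moderate	0.71	24	normal	0	literature_ref18
5	N187K	c.561C>A	p.Asn187Lys	missense	187	FBD_CS	F	62	none	severe	1.60	12	moderate	3	literature_ref18
6	I194S	c.581T>G	p.Ile194Ser	missense	194	FBD_CS	F	72	yes	moderate	1.25	10	moderate	4	literature_ref18
7	F215L	c.645C>A	p.Phe215Leu	missense	215	FBD	F	84	yes	mild	0.56	42	mild	1	our_case
8	R230H	c.689G>A	p.Arg230His	missense	230	FBD	F	96	yes	moderate	1.00	96	moderate	4	literature_ref40
9	L235H	c.704T>A	p.Leu235His	missense	235	FBD	M	16	yes	moderate	0.79	9	severe	6	our_case
10	G252V	c.755G>T	p.Gly252Val	missense	252	FBD	F	108	yes	moderate	0.75	19	moderate	4	literature_ref17
11	G252D	c.755G>A	p.Gly252Asp	missense	252	FBD	F	192	yes	severe	1.47	192	mild	1	literature_ref18
12	W255Lfs*156	c.763_893del	p.Trp255LeufsTer156	frameshift	255	FBD	M	49	yes	moderate	1.31	22	severe	6	our_case
13	Y307X	c.921C>G	p.Tyr307Ter	nonsense	307	C_terminal	F	33	yes	moderate	1.29	6	severe	5	literature_ref18
14	Y416X	c.1248C>G	p.Tyr416Ter	nonsense	416	C_terminal	F	60	yes	moderate	1.20	22	moderate	4	literature_ref39
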