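metabolite_code	parent_code	mw_metabolite	mw_parent	fue	analyte_class	is_edi_eligible
MMP	DMP	180.16	194.18	0.69	phthalate	TRUE
MEP	DEP	194.18	222.24	0.69	phthalate	TRUE
MiBP	DiBP	222.24	278.34	0.70	phthalate	TRUE
MnBP	DnBP	222.24	278.34	0.69	phthalate	TRUE
MBzP	BBzP	256.25	312.36	0.73	phthalate	TRUE
MEHP	DEHP	278.34	390.56	0.059	phthalate	TRUE
MEHHP	DEHP	294.34	390.56	0.149	phthalate	TRUE
MEOHP	DEHP	292.33	390.56	0.109	phthalate	TRUE
MECPP	DEHP	308.33	390.56	0.132	phthalate	TRUE
MCPP	MCPP	252.22	252.22	1.00	phthalate	FALSE
BPA	BPA	228.29	228.29	1.00	bisphenol	TRUE
BPS	BPS	250.27	250.27	1.00	bisphenol	TRUE
BPF	BPF	200.23	200.23	1.00	bisphenol	TRUE
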