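aa	chi	a1	a2	a3	a4	symmetric
ARG	1	N	CA	CB	CG	0
ARG	2	CA	CB	CG	CD	0
ARG	3	CB	CG	CD	NE	0
ARG	4	CG	CD	NE	CZ	0
ASN	1	N	CA	CB	CG	0
ASN	2	CA	CB	CG	OD1	0
ASP	1	N	CA	CB	CG	0
ASP	2	CA	CB	CG	OD1	1
CYS	1	N	CA	CB	SG	0
GLN	1	N	CA	CB	CG	0
GLN	2	CA	CB	CG	CD	0
GLN	3	CB	CG	CD	OE1	0
GLU	1	N	CA	CB	CG	0
GLU	2	CA	CB	CG	CD	0
GLU	3	CB	CG	CD	OE1	1
HIS	1	N	CA	CB	CG	0
HIS	2	CA	CB	CG	ND1	0
ILE	1	N	CA	CB	CG1	0
ILE	2	CA	CB	CG1	CD1	0
LEU	1	N	CA	CB	CG	0
LEU	2	CA	CB	CG	CD1	0
LYS	1	N	CA	CB	CG	0
LYS	2	CA	CB	CG	CD	0
LYS	3	CB	CG	CD	CE	0
LYS	4	CG	CD	CE	NZ	0
MET	1	N	CA	CB	CG	0
MET	2	CA	CB	CG	SD	0
MET	3	CB	CG	SD	CE	0
PHE	1	N	CA	CB	CG	0
PHE	2	CA	CB	CG	CD1	1
PRO	1	N	CA	CB	CG	0
PRO	2	CA	CB	CG	CD	0
SER	1	N	CA	CB	OG	0
THR	1	N	CA	CB	OG1	0
TRP	1	N	CA	CB	CG	0
TRP	2	CA	CB	CG	CD1	0
TYR	1	N	CA	CB	CG	0
TYR	2	CA	CB	CG	CD1	1
VAL	1	N	CA	CB	CG1	0
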