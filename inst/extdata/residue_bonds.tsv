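aa	atom1	atom2
ALA	N	CA
ALA	CA	C
ALA	CA	CB
ALA	C	O
ARG	N	CA
ARG	CA	C
ARG	CA	CB
ARG	C	O
ARG	CB	CG
ARG	CG	CD
ARG	CD	NE
ARG	NE	CZ
ARG	CZ	NH1
ARG	CZ	NH2
ASN	N	CA
ASN	CA	C
ASN	CA	CB
ASN	C	O
ASN	CB	CG
ASN	CG	OD1
ASN	CG	ND2
ASP	N	CA
ASP	CA	C
ASP	CA	CB
ASP	C	O
ASP	CB	CG
ASP	CG	OD1
ASP	CG	OD2
CYS	N	CA
CYS	CA	C
CYS	CA	CB
CYS	C	O
CYS	CB	SG
GLN	N	CA
GLN	CA	C
GLN	CA	CB
GLN	C	O
GLN	CB	CG
GLN	CG	CD
GLN	CD	OE1
GLN	CD	NE2
GLU	N	CA
GLU	CA	C
GLU	CA	CB
GLU	C	O
GLU	CB	CG
GLU	CG	CD
GLU	CD	OE1
GLU	CD	OE2
GLY	N	CA
GLY	CA	C
GLY	C	O
HIS	N	CA
HIS	CA	C
HIS	CA	CB
HIS	C	O
HIS	CB	CG
HIS	CG	ND1
HIS	CG	CD2
HIS	ND1	CE1
HIS	CD2	NE2
HIS	CE1	NE2
ILE	N	CA
ILE	CA	C
ILE	CA	CB
ILE	C	O
ILE	CB	CG1
ILE	CB	CG2
ILE	CG1	CD1
LEU	N	CA
LEU	CA	C
LEU	CA	CB
LEU	C	O
LEU	CB	CG
LEU	CG	CD1
LEU	CG	CD2
LYS	N	CA
LYS	CA	C
LYS	CA	CB
LYS	C	O
LYS	CB	CG
LYS	CG	CD
LYS	CD	CE
LYS	CE	NZ
MET	N	CA
MET	CA	C
MET	CA	CB
MET	C	O
MET	CB	CG
MET	CG	SD
MET	SD	CE
PHE	N	CA
PHE	CA	C
PHE	CA	CB
PHE	C	O
PHE	CB	CG
PHE	CG	CD1
PHE	CG	CD2
PHE	CD1	CE1
PHE	CD2	CE2
PHE	CE1	CZ
PHE	CE2	CZ
PRO	N	CA
PRO	N	CD
PRO	CA	C
PRO	CA	CB
PRO	C	O
PRO	CB	CG
PRO	CG	CD
SER	N	CA
SER	CA	C
SER	CA	CB
SER	C	O
SER	CB	OG
THR	N	CA
THR	CA	C
THR	CA	CB
THR	C	O
THR	CB	OG1
THR	CB	CG2
TRP	N	CA
TRP	CA	C
TRP	CA	CB
TRP	C	O
TRP	CB	CG
TRP	CG	CD1
TRP	CG	CD2
TRP	CD1	NE1
TRP	CD2	CE2
TRP	CD2	CE3
TRP	NE1	CE2
TRP	CE2	CZ2
TRP	CE3	CZ3
TRP	CZ2	CH2
TRP	CZ3	CH2
TYR	N	CA
TYR	CA	C
TYR	CA	CB
TYR	C	O
TYR	CB	CG
TYR	CG	CD1
TYR	CG	CD2
TYR	CD1	CE1
TYR	CD2	CE2
TYR	CE1	CZ
TYR	CE2	CZ
TYR	CZ	OH
VAL	N	CA
VAL	CA	C
VAL	CA	CB
VAL	C	O
VAL	CB	CG1
VAL	CB	CG2
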