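aa	slot	atom	element	x	y	z
ALA	1	N	N	-0.9660	0.4930	1.5000
ALA	2	CA	C	0.2570	0.4180	0.6920
ALA	3	C	C	-0.0940	0.0170	-0.7160
ALA	4	O	O	-1.0560	-0.6820	-0.9230
ALA	5	CB	C	1.2040	-0.6200	1.2960
ARG	1	N	N	-0.4690	1.1100	-0.9930
ARG	2	CA	C	0.0040	2.2940	-1.7080
ARG	3	C	C	-0.9070	2.5210	-2.9010
ARG	4	O	O	-1.8270	1.7890	-3.2420
ARG	5	CB	C	1.4750	2.1500	-2.1270
ARG	6	CG	C	1.7450	1.0170	-3.1300
ARG	7	CD	C	3.2100	0.9540	-3.5570
ARG	8	NE	N	4.0710	0.7260	-2.4210
ARG	9	CZ	C	5.4690	0.6240	-2.5280
ARG	10	NH1	N	6.2590	0.4040	-1.4050
ARG	11	NH2	N	6.0780	0.7440	-3.7730
ASN	1	N	N	-0.2930	1.6860	0.0940
ASN	2	CA	C	-0.4480	0.2920	-0.3400
ASN	3	C	C	-1.8460	-0.1790	-0.0310
ASN	4	O	O	-2.5100	0.4020	0.7940
ASN	5	CB	C	0.5620	-0.5880	0.4010
ASN	6	CG	C	1.9600	-0.1970	-0.0020
ASN	7	OD1	O	2.1320	0.6970	-0.8040
ASN	8	ND2	N	3.0190	-0.8410	0.5270
ASP	1	N	N	-0.3170	1.6880	0.0660
ASP	2	CA	C	-0.4700	0.2860	-0.3440
ASP	3	C	C	-1.8680	-0.1800	-0.0290
ASP	4	O	O	-2.5340	0.4150	0.7860
ASP	5	CB	C	0.5390	-0.5800	0.4130
ASP	6	CG	C	1.9380	-0.1950	0.0040
ASP	7	OD1	O	2.1090	0.6810	-0.8100
ASP	8	OD2	O	2.9920	-0.8260	0.5430
CYS	1	N	N	1.5850	0.4830	-0.0810
CYS	2	CA	C	0.1410	0.4500	0.1860
CYS	3	C	C	-0.0950	0.0060	1.6060
CYS	4	O	O	0.6850	-0.7420	2.1430
CYS	5	CB	C	-0.5330	-0.5300	-0.7740
CYS	6	SG	S	-0.2470	0.0040	-2.4840
GLN	1	N	N	1.8580	-0.1480	1.1250
GLN	2	CA	C	0.5170	0.4510	1.1120
GLN	3	C	C	-0.2360	0.0220	2.3440
GLN	4	O	O	-0.0050	-1.0490	2.8510
GLN	5	CB	C	-0.2360	-0.0130	-0.1350
GLN	6	CG	C	0.5290	0.4210	-1.3850
GLN	7	CD	C	-0.2130	-0.0360	-2.6140
GLN	8	OE1	O	-1.2520	-0.6500	-2.5000
GLN	9	NE2	N	0.2770	0.2360	-3.8390
GLU	1	N	N	1.1990	1.8670	-0.1170
GLU	2	CA	C	1.1380	0.5150	0.4530
GLU	3	C	C	2.3640	-0.2600	0.0410
GLU	4	O	O	3.0100	0.0960	-0.9160
GLU	5	CB	C	-0.1130	-0.2000	-0.0620
GLU	6	CG	C	-1.3600	0.5170	0.4610
GLU	7	CD	C	-2.5930	-0.1870	-0.0460
GLU	8	OE1	O	-2.4850	-1.1610	-0.7530
GLU	9	OE2	O	-3.8110	0.2690	0.2870
GLY	1	N	N	1.9310	0.0900	-0.0340
GLY	2	CA	C	0.7610	-0.7990	-0.0080
GLY	3	C	C	-0.4980	0.0290	-0.0050
GLY	4	O	O	-0.4290	1.2350	-0.0230
HIS	1	N	N	-0.0400	-1.2100	0.0530
HIS	2	CA	C	1.1720	-1.7090	0.6520
HIS	3	C	C	1.0830	-3.2070	0.9050
HIS	4	O	O	0.0400	-3.7700	1.2220
HIS	5	CB	C	1.4840	-0.9750	1.9620
HIS	6	CG	C	2.9400	-1.0600	2.3530
HIS	7	ND1	N	3.3800	-2.0750	3.1290
HIS	8	CD2	C	3.9600	-0.2510	2.0460
HIS	9	CE1	C	4.6930	-1.9080	3.3170
HIS	10	NE2	N	5.0580	-0.8010	2.6620
ILE	1	N	N	-1.9440	0.3350	-0.3430
ILE	2	CA	C	-0.4870	0.5190	-0.3690
ILE	3	C	C	0.0660	-0.0320	-1.6570
ILE	4	O	O	-0.4840	-0.9580	-2.2030
ILE	5	CB	C	0.1400	-0.2190	0.8140
ILE	6	CG1	C	-0.4210	0.3410	2.1220
ILE	7	CG2	C	1.6580	-0.0270	0.7880
ILE	8	CD1	C	0.2060	-0.3970	3.3050
LEU	1	N	N	-1.6610	0.6270	-0.4060
LEU	2	CA	C	-0.2050	0.4410	-0.4670
LEU	3	C	C	0.1800	-0.0550	-1.8360
LEU	4	O	O	-0.5910	-0.7310	-2.4740
LEU	5	CB	C	0.2210	-0.5830	0.5850
LEU	6	CG	C	-0.1700	-0.0790	1.9760
LEU	7	CD1	C	0.2560	-1.1040	3.0290
LEU	8	CD2	C	0.5260	1.2540	2.2500
LYS	1	N	N	1.4220	1.7960	0.1980
LYS	2	CA	C	1.3940	0.3550	0.4840
LYS	3	C	C	2.6570	-0.2840	-0.0320
LYS	4	O	O	3.3160	0.2750	-0.8760
LYS	5	CB	C	0.1840	-0.2780	-0.2060
LYS	6	CG	C	-1.1020	0.2820	0.4070
LYS	7	CD	C	-2.3130	-0.3510	-0.2830
LYS	8	CE	C	-3.5980	0.2080	0.3290
LYS	9	NZ	N	-4.7610	-0.4000	-0.3320
MET	1	N	N	-1.8160	0.1420	-1.1660
MET	2	CA	C	-0.3920	0.4990	-1.2140
MET	3	C	C	0.2060	0.0020	-2.5040
MET	4	O	O	-0.2360	-0.9890	-3.0330
MET	5	CB	C	0.3340	-0.1450	-0.0320
MET	6	CG	C	-0.2730	0.3590	1.2770
MET	7	SD	S	0.5890	-0.4050	2.6780
MET	8	CE	C	-0.3140	0.3530	4.0560
PHE	1	N	N	1.3170	0.9620	1.0140
PHE	2	CA	C	-0.0200	0.4260	1.3000
PHE	3	C	C	-0.1090	0.0470	2.7560
PHE	4	O	O	0.8790	-0.3170	3.3460
PHE	5	CB	C	-0.2700	-0.8090	0.4340
PHE	6	CG	C	-0.1810	-0.4300	-1.0200
PHE	7	CD1	C	1.0310	-0.4980	-1.6800
PHE	8	CD2	C	-1.3140	-0.0180	-1.6980
PHE	9	CE1	C	1.1120	-0.1500	-3.0150
PHE	10	CE2	C	-1.2310	0.3330	-3.0320
PHE	11	CZ	C	-0.0180	0.2650	-3.6910
PRO	1	N	N	-0.8160	1.1080	0.2540
PRO	2	CA	C	0.0010	-0.1070	0.5090
PRO	3	C	C	1.4080	0.0910	0.0050
PRO	4	O	O	1.6500	0.9800	-0.7770
PRO	5	CB	C	-0.7030	-1.2270	-0.2860
PRO	6	CG	C	-2.1630	-0.7530	-0.4390
PRO	7	CD	C	-2.2180	0.6140	0.2760
SER	1	N	N	1.5250	0.4930	-0.6080
SER	2	CA	C	0.1000	0.4690	-0.2520
SER	3	C	C	-0.0530	0.0040	1.1730
SER	4	O	O	0.7510	-0.7600	1.6490
SER	5	CB	C	-0.6420	-0.4890	-1.1840
SER	6	OG	O	-0.4960	-0.0490	-2.5350
THR	1	N	N	1.5430	-0.7020	0.4300
THR	2	CA	C	0.1220	-0.7060	0.0560
THR	3	C	C	-0.0380	-0.0900	-1.3090
THR	4	O	O	0.7320	0.7610	-1.6830
THR	5	CB	C	-0.6750	0.1040	1.0790
THR	6	OG1	O	-0.1930	1.4480	1.1030
THR	7	CG2	C	-0.5110	-0.5210	2.4660
TRP	1	N	N	1.2780	1.1210	2.0590
TRP	2	CA	C	-0.0080	0.4170	1.9700
TRP	3	C	C	-0.4900	0.0760	3.3570
TRP	4	O	O	0.3080	-0.1300	4.2400
TRP	5	CB	C	0.1680	-0.8680	1.1610
TRP	6	CG	C	0.6500	-0.5260	-0.2250
TRP	7	CD1	C	1.9280	-0.4180	-0.6220
TRP	8	CD2	C	-0.1860	-0.2560	-1.3960
TRP	9	NE1	N	1.9780	-0.0950	-1.9510
TRP	10	CE2	C	0.7010	0.0140	-2.4540
TRP	11	CE3	C	-1.5640	-0.2100	-1.6150
TRP	12	CZ2	C	0.1900	0.3140	-3.7120
TRP	13	CZ3	C	-2.0440	0.0860	-2.8590
TRP	14	CH2	C	-1.1730	0.3480	-3.9070
TYR	1	N	N	1.3200	0.9520	1.4280
TYR	2	CA	C	-0.0180	0.4290	1.7340
TYR	3	C	C	-0.1030	0.0940	3.2010
TYR	4	O	O	0.8860	-0.2540	3.7990
TYR	5	CB	C	-0.2740	-0.8310	0.9070
TYR	6	CG	C	-0.1890	-0.4960	-0.5590
TYR	7	CD1	C	1.0220	-0.5890	-1.2190
TYR	8	CD2	C	-1.3240	-0.1020	-1.2440
TYR	9	CE1	C	1.1030	-0.2820	-2.5630
TYR	10	CE2	C	-1.2470	0.2100	-2.5870
TYR	11	CZ	C	-0.0320	0.1180	-3.2520
TYR	12	OH	O	0.0440	0.4200	-4.5740
VAL	1	N	N	1.5640	-0.6420	0.4540
VAL	2	CA	C	0.1450	-0.6980	0.0790
VAL	3	C	C	-0.0370	-0.0930	-1.2880
VAL	4	O	O	0.7030	0.7840	-1.6640
VAL	5	CB	C	-0.6820	0.0860	1.0980
VAL	6	CG1	C	-0.4970	-0.5280	2.4870
VAL	7	CG2	C	-0.2180	1.5430	1.1190
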