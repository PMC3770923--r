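template	atom	charge	rmin2	eps	born	formal
GLY	N	-0.35	1.85	0.200	1.55	0
GLY	CA	0.10	2.00	0.100	1.70	0
GLY	C	0.55	2.00	0.100	1.70	0
GLY	O	-0.55	1.70	0.120	1.50	0
GLY	H	0.25	0.80	0.046	1.30	0
ALA	N	-0.35	1.85	0.200	1.55	0
ALA	CA	0.10	2.00	0.100	1.70	0
ALA	C	0.55	2.00	0.100	1.70	0
ALA	O	-0.55	1.70	0.120	1.50	0
ALA	H	0.25	0.80	0.046	1.30	0
ALA	CB	0.00	2.00	0.100	1.70	0
SER	N	-0.35	1.85	0.200	1.55	0
SER	CA	0.10	2.00	0.100	1.70	0
SER	C	0.55	2.00	0.100	1.70	0
SER	O	-0.55	1.70	0.120	1.50	0
SER	H	0.25	0.80	0.046	1.30	0
SER	CB	0.25	2.00	0.100	1.70	0
SER	OG	-0.65	1.70	0.120	1.50	0
SER	HG	0.40	0.80	0.046	1.30	0
CYS	N	-0.35	1.85	0.200	1.55	0
CYS	CA	0.10	2.00	0.100	1.70	0
CYS	C	0.55	2.00	0.100	1.70	0
CYS	O	-0.55	1.70	0.120	1.50	0
CYS	H	0.25	0.80	0.046	1.30	0
CYS	CB	0.10	2.00	0.100	1.70	0
CYS	SG	-0.45	2.00	0.450	1.80	0
CYS	HG	0.35	0.80	0.046	1.30	0
THR	N	-0.35	1.85	0.200	1.55	0
THR	CA	0.10	2.00	0.100	1.70	0
THR	C	0.55	2.00	0.100	1.70	0
THR	O	-0.55	1.70	0.120	1.50	0
THR	H	0.25	0.80	0.046	1.30	0
THR	CB	0.25	2.00	0.100	1.70	0
THR	OG1	-0.65	1.70	0.120	1.50	0
THR	CG2	0.00	2.00	0.100	1.70	0
THR	HG1	0.40	0.80	0.046	1.30	0
VAL	N	-0.35	1.85	0.200	1.55	0
VAL	CA	0.10	2.00	0.100	1.70	0
VAL	C	0.55	2.00	0.100	1.70	0
VAL	O	-0.55	1.70	0.120	1.50	0
VAL	H	0.25	0.80	0.046	1.30	0
VAL	CB	0.00	2.00	0.100	1.70	0
VAL	CG1	0.00	2.00	0.100	1.70	0
VAL	CG2	0.00	2.00	0.100	1.70	0
LEU	N	-0.35	1.85	0.200	1.55	0
LEU	CA	0.10	2.00	0.100	1.70	0
LEU	C	0.55	2.00	0.100	1.70	0
LEU	O	-0.55	1.70	0.120	1.50	0
LEU	H	0.25	0.80	0.046	1.30	0
LEU	CB	0.00	2.00	0.100	1.70	0
LEU	CG	0.00	2.00	0.100	1.70	0
LEU	CD1	0.00	2.00	0.100	1.70	0
LEU	CD2	0.00	2.00	0.100	1.70	0
ILE	N	-0.35	1.85	0.200	1.55	0
ILE	CA	0.10	2.00	0.100	1.70	0
ILE	C	0.55	2.00	0.100	1.70	0
ILE	O	-0.55	1.70	0.120	1.50	0
ILE	H	0.25	0.80	0.046	1.30	0
ILE	CB	0.00	2.00	0.100	1.70	0
ILE	CG1	0.00	2.00	0.100	1.70	0
ILE	CG2	0.00	2.00	0.100	1.70	0
ILE	CD1	0.00	2.00	0.100	1.70	0
MET	N	-0.35	1.85	0.200	1.55	0
MET	CA	0.10	2.00	0.100	1.70	0
MET	C	0.55	2.00	0.100	1.70	0
MET	O	-0.55	1.70	0.120	1.50	0
MET	H	0.25	0.80	0.046	1.30	0
MET	CB	0.00	2.00	0.100	1.70	0
MET	CG	0.06	2.00	0.100	1.70	0
MET	SD	-0.12	2.00	0.450	1.80	0
MET	CE	0.06	2.00	0.100	1.70	0
PRO	N	-0.20	1.85	0.200	1.55	0
PRO	CA	0.10	2.00	0.100	1.70	0
PRO	C	0.55	2.00	0.100	1.70	0
PRO	O	-0.55	1.70	0.120	1.50	0
PRO	CB	0.00	2.00	0.100	1.70	0
PRO	CG	0.00	2.00	0.100	1.70	0
PRO	CD	0.10	2.00	0.100	1.70	0
PHE	N	-0.35	1.85	0.200	1.55	0
PHE	CA	0.10	2.00	0.100	1.70	0
PHE	C	0.55	2.00	0.100	1.70	0
PHE	O	-0.55	1.70	0.120	1.50	0
PHE	H	0.25	0.80	0.046	1.30	0
PHE	CB	0.00	2.00	0.100	1.70	0
PHE	CG	0.00	2.00	0.100	1.70	0
PHE	CD1	0.00	2.00	0.100	1.70	0
PHE	CD2	0.00	2.00	0.100	1.70	0
PHE	CE1	0.00	2.00	0.100	1.70	0
PHE	CE2	0.00	2.00	0.100	1.70	0
PHE	CZ	0.00	2.00	0.100	1.70	0
TYR	N	-0.35	1.85	0.200	1.55	0
TYR	CA	0.10	2.00	0.100	1.70	0
TYR	C	0.55	2.00	0.100	1.70	0
TYR	O	-0.55	1.70	0.120	1.50	0
TYR	H	0.25	0.80	0.046	1.30	0
TYR	CB	0.00	2.00	0.100	1.70	0
TYR	CG	0.00	2.00	0.100	1.70	0
TYR	CD1	0.00	2.00	0.100	1.70	0
TYR	CD2	0.00	2.00	0.100	1.70	0
TYR	CE1	0.00	2.00	0.100	1.70	0
TYR	CE2	0.00	2.00	0.100	1.70	0
TYR	CZ	0.25	2.00	0.100	1.70	0
TYR	OH	-0.65	1.70	0.120	1.50	0
TYR	HH	0.40	0.80	0.046	1.30	0
TRP	N	-0.35	1.85	0.200	1.55	0
TRP	CA	0.10	2.00	0.100	1.70	0
TRP	C	0.55	2.00	0.100	1.70	0
TRP	O	-0.55	1.70	0.120	1.50	0
TRP	H	0.25	0.80	0.046	1.30	0
TRP	CB	0.00	2.00	0.100	1.70	0
TRP	CG	0.00	2.00	0.100	1.70	0
TRP	CD1	0.06	2.00	0.100	1.70	0
TRP	CD2	0.00	2.00	0.100	1.70	0
TRP	NE1	-0.36	1.85	0.200	1.55	0
TRP	CE2	0.00	2.00	0.100	1.70	0
TRP	CE3	0.00	2.00	0.100	1.70	0
TRP	CZ2	0.00	2.00	0.100	1.70	0
TRP	CZ3	0.00	2.00	0.100	1.70	0
TRP	CH2	0.00	2.00	0.100	1.70	0
TRP	HE1	0.30	0.80	0.046	1.30	0
ASP	N	-0.35	1.85	0.200	1.55	-1
ASP	CA	0.10	2.00	0.100	1.70	-1
ASP	C	0.55	2.00	0.100	1.70	-1
ASP	O	-0.55	1.70	0.120	1.50	-1
ASP	H	0.25	0.80	0.046	1.30	-1
ASP	CB	-0.16	2.00	0.100	1.70	-1
ASP	CG	0.36	2.00	0.100	1.70	-1
ASP	OD1	-0.60	1.70	0.120	1.50	-1
ASP	OD2	-0.60	1.70	0.120	1.50	-1
ASN	N	-0.35	1.85	0.200	1.55	0
ASN	CA	0.10	2.00	0.100	1.70	0
ASN	C	0.55	2.00	0.100	1.70	0
ASN	O	-0.55	1.70	0.120	1.50	0
ASN	H	0.25	0.80	0.046	1.30	0
ASN	CB	0.00	2.00	0.100	1.70	0
ASN	CG	0.55	2.00	0.100	1.70	0
ASN	OD1	-0.55	1.70	0.120	1.50	0
ASN	ND2	-0.60	1.85	0.200	1.55	0
ASN	HD21	0.30	0.80	0.046	1.30	0
ASN	HD22	0.30	0.80	0.046	1.30	0
GLU	N	-0.35	1.85	0.200	1.55	-1
GLU	CA	0.10	2.00	0.100	1.70	-1
GLU	C	0.55	2.00	0.100	1.70	-1
GLU	O	-0.55	1.70	0.120	1.50	-1
GLU	H	0.25	0.80	0.046	1.30	-1
GLU	CB	0.00	2.00	0.100	1.70	-1
GLU	CG	-0.16	2.00	0.100	1.70	-1
GLU	CD	0.36	2.00	0.100	1.70	-1
GLU	OE1	-0.60	1.70	0.120	1.50	-1
GLU	OE2	-0.60	1.70	0.120	1.50	-1
GLN	N	-0.35	1.85	0.200	1.55	0
GLN	CA	0.10	2.00	0.100	1.70	0
GLN	C	0.55	2.00	0.100	1.70	0
GLN	O	-0.55	1.70	0.120	1.50	0
GLN	H	0.25	0.80	0.046	1.30	0
GLN	CB	0.00	2.00	0.100	1.70	0
GLN	CG	0.00	2.00	0.100	1.70	0
GLN	CD	0.55	2.00	0.100	1.70	0
GLN	OE1	-0.55	1.70	0.120	1.50	0
GLN	NE2	-0.60	1.85	0.200	1.55	0
GLN	HE21	0.30	0.80	0.046	1.30	0
GLN	HE22	0.30	0.80	0.046	1.30	0
LYS	N	-0.35	1.85	0.200	1.55	1
LYS	CA	0.10	2.00	0.100	1.70	1
LYS	C	0.55	2.00	0.100	1.70	1
LYS	O	-0.55	1.70	0.120	1.50	1
LYS	H	0.25	0.80	0.046	1.30	1
LYS	CB	0.00	2.00	0.100	1.70	1
LYS	CG	0.00	2.00	0.100	1.70	1
LYS	CD	0.00	2.00	0.100	1.70	1
LYS	CE	0.25	2.00	0.100	1.70	1
LYS	NZ	-0.30	1.85	0.200	1.55	1
LYS	HZ1	0.35	0.80	0.046	1.30	1
LYS	HZ2	0.35	0.80	0.046	1.30	1
LYS	HZ3	0.35	0.80	0.046	1.30	1
ARG	N	-0.35	1.85	0.200	1.55	1
ARG	CA	0.10	2.00	0.100	1.70	1
ARG	C	0.55	2.00	0.100	1.70	1
ARG	O	-0.55	1.70	0.120	1.50	1
ARG	H	0.25	0.80	0.046	1.30	1
ARG	CB	0.00	2.00	0.100	1.70	1
ARG	CG	0.00	2.00	0.100	1.70	1
ARG	CD	0.10	2.00	0.100	1.70	1
ARG	NE	-0.40	1.85	0.200	1.55	1
ARG	CZ	0.50	2.00	0.100	1.70	1
ARG	HE	0.30	0.80	0.046	1.30	1
ARG	NH1	-0.45	1.85	0.200	1.55	1
ARG	NH2	-0.45	1.85	0.200	1.55	1
ARG	HH11	0.35	0.80	0.046	1.30	1
ARG	HH12	0.35	0.80	0.046	1.30	1
ARG	HH21	0.35	0.80	0.046	1.30	1
ARG	HH22	0.35	0.80	0.046	1.30	1
HIS	N	-0.35	1.85	0.200	1.55	0
HIS	CA	0.10	2.00	0.100	1.70	0
HIS	C	0.55	2.00	0.100	1.70	0
HIS	O	-0.55	1.70	0.120	1.50	0
HIS	H	0.25	0.80	0.046	1.30	0
HIS	CB	0.00	2.00	0.100	1.70	0
HIS	CG	0.11	2.00	0.100	1.70	0
HIS	ND1	-0.36	1.85	0.200	1.55	0
HIS	CD2	0.10	2.00	0.100	1.70	0
HIS	CE1	0.25	2.00	0.100	1.70	0
HIS	NE2	-0.40	1.85	0.200	1.55	0
HIS	HD1	0.30	0.80	0.046	1.30	0
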