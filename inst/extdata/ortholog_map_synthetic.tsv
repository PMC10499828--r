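human_symbol	mouse_symbol
CXCL9	Cxcl9
CXCL10	Cxcl10
CXCL11	Cxcl11
PRF1	Prf1
CD2	Cd2
CD3D	Cd3d
CD8A	Cd8a
IDO1	Ido1
STAT1	Stat1
GBP5	Gbp5
CCL5	Ccl5
IFNG	Ifng
LAG3	Lag3
CTLA4	Ctla4
TIGIT	Tigit
NKG7	Nkg7
SOX8	Sox8
VTCN1	Vtcn1
FOXC1	Foxc1
MIA	Mia
ELF5	Elf5
GABRP	Gabrp
KRT16	Krt16
SFRP1	Sfrp1
TTYH1	Ttyh1
COL9A3	Col9a3
HORMAD1	Hormad1
OPRK1	Oprk1
TUBB2B	Tubb2b
FOXA1	Foxa1
KRT18	Krt18
SPDEF	Spdef
PIP	Pip
AGR2	Agr2
TFF1	Tff1
TFF3	Tff3
XBP1	Xbp1
CA12	Ca12
DHRS2	Dhrs2
AZGP1	Azgp1
SCUBE2	Scube2
GATA3	Gata3
TOX3	Tox3
ANKRD30A	Ankrd30a
PGR	Pgr
COL1A1	Col1a1
FBN1	Fbn1
THBS2	Thbs2
POSTN	Postn
ZEB1	Zeb1
TWIST1	Twist1
PDGFRB	Pdgfrb
FAP	Fap
ACTA2	Acta2
TAGLN	Tagln
VCAN	Vcan
DCN	Dcn
FN1	Fn1
CDH11	Cdh11
NID2	Nid2
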