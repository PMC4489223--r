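nonstandard	standard
# conventional parent assignments for common modified residues
MSE	MET
SEC	CYS
PYL	LYS
SEP	SER
TPO	THR
PTR	TYR
CSO	CYS
CSS	CYS
CME	CYS
CSD	CYS
OCS	CYS
MLY	LYS
M3L	LYS
ALY	LYS
KCX	LYS
LLP	LYS
HYP	PRO
PCA	GLU
CGU	GLU
MLE	LEU
NLE	LEU
AIB	ALA
DAL	ALA
DAR	ARG
DSG	ASN
DSP	ASP
DCY	CYS
DGN	GLN
DGL	GLU
DHI	HIS
DIL	ILE
DLE	LEU
DLY	LYS
MED	MET
DPN	PHE
DPR	PRO
DSN	SER
DTH	THR
DTR	TRP
DTY	TYR
DVA	VAL
FME	MET
SAR	GLY
MVA	VAL
HIC	HIS
NEP	HIS
MHO	MET
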