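# Modified / non-standard residues resolved to a parent standard residue
# before label lookup. Fully user-overridable.
alias	aa3
MSE	MET
TPO	THR
SEP	SER
PTR	TYR
TYN	TYR
TYS	TYR
MLY	LYS
HYP	PRO
CSO	CYS
CME	CYS
KCX	LYS
PCA	GLU
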