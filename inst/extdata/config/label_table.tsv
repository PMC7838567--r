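# Default amino-acid -> integer label mapping.
# Alphabetical three-letter-code order mapped to 4..23; m = 23.
# NOTE: absolute key integers are only comparable across key files generated
# with the same mapping and bin boundaries.
aa3	label
ALA	4
ARG	5
ASN	6
ASP	7
CYS	8
GLN	9
GLU	10
GLY	11
HIS	12
ILE	13
LEU	14
LYS	15
MET	16
PHE	17
PRO	18
SER	19
THR	20
TRP	21
TYR	22
VAL	23
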