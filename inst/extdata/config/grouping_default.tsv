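# Default amino-acid grouping: structurally similar residues share a label.
# Group label = smallest member label (stays within 1..m).
aa3	group
SER	19
THR	19
ASP	7
GLU	7
ASN	6
GLN	6
LYS	5
ARG	5
ILE	13
LEU	13
VAL	13
PHE	17
TYR	17
TRP	17
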