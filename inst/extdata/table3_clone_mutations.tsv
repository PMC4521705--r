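# Target-gene (PMR1) mutations in sequenced NaCl-resistant clones from
# compatible (C) and incompatible (I) lines at transfers 10 and 16, as
# published. The trailing '*' marks a substitution 220 bp upstream of the
# start codon. The printed table has 38 rows (the accompanying text says 37
# clones and 25 Sanger-sequenced; the table is reproduced verbatim).
line	clone	method	mutation	aa_change
C10	A	WGS	C2027T	A676V
C10	B	WGS	None	n/a
C10	C	WGS	None	n/a
C10	D	Sanger, PMR1 PCR	None	n/a
C10	E	Sanger, PMR1 PCR	None	n/a
C10	F	Sanger, PMR1 PCR	None	n/a
C10	K	Sanger, PMR1 PCR	None	n/a
C10	L	Sanger, PMR1 PCR	None	n/a
C10	M	Sanger, PMR1 PCR	None	n/a
C10	N	Sanger, PMR1 PCR	A778C	T260P
C16	A	WGS	C2027T	A676V
C16	G	WGS	T-220A*
C16	H	Sanger, PMR1 PCR	G1348T	D450Y
C16	I	Sanger, PMR1 PCR	G1121T	G374V
C16	J	Sanger, PMR1 PCR	C1532T	S511F
C16	N	Sanger, PMR1 PCR	A778C	T260P
I10	A	WGS	T459A	C153stop
I10	B	WGS	T412C	S138P
I10	C	WGS	T2G	start codon disruption
I10	D	WGS	T2213C	F738S
I10	E	WGS	A1349T	D450V
I10	F	Sanger, PMR1 PCR	A557G	D186G
I10	G	Sanger, PMR1 PCR	G533C	R178T
I10	I	Sanger, PMR1 PCR	+ 2(AA) at bp 658	frameshift, amino acid 220
I10	J	Sanger, PMR1 PCR	A631G	K211E
I10	K	Sanger, PMR1 PCR	A1981C	K661Q
I10	L	Sanger, PMR1 PCR	C1508T	A503V
I10	M	Sanger, PMR1 PCR	G1051C	A351P
I10	Q	Sanger, PMR1 PCR	none	n/a
I10	O	Sanger, PMR1 PCR	none	n/a
I16	F	Sanger, PMR1 PCR	A557G	D186G
I16	H	WGS	C554T	A185V
I16	D	WGS	G3T	start codon disruption
I16	B	Sanger, PMR1 PCR	T412C	S138P
I16	I	Sanger, PMR1 PCR	+ 2(AA) at bp 658	frameshift, amino acid 220
I16	N	Sanger, PMR1 PCR	T2062G	L688V
I16	O	Sanger, PMR1 PCR	none	n/a
I16	P	Sanger, PMR1 PCR	G2031T	M677I
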