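# Bulk-segregant pooled read counts: evolved NaCl-resistant clones (transfer 10)
# crossed to unevolved strains; resistant (r) and sensitive (s) spore pools
# sequenced. One row per candidate SNP. 'linkage' is the published call.
line	chrom	pos	cds_mutation	ref_allele	alt_allele	r_wt	r_snp	s_wt	s_snp	linkage
I10A	chrVII	190010	T459A	A	T	1	58	54	1	Yes
I10A	chrVIII	555937		A	G	29	13	29	35	No
I10B	chrII	48117		C	T	42	51	29	28	No
I10B	chrVII	190057	T412C	A	G	0	91	50	0	Yes
I10C	chrIV	13937		G	A	50	40	55	46	No
I10C	chrVII	190467	T2G	A	C	0	14	91	0	Yes
I10C	chrXIII	908203		G	A	11	18	86	61	No
C10A	chrVII	188442	C2027T	G	A	0	70	104	6	Yes
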