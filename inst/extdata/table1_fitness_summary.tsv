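# Published competition-fitness summary: mean relative fitness w of the
# incompatible (mutator) population against the compatible reference after
# the indicated number of serial transfers, +/- SEM over n competitions,
# in plain rich medium (YPD) and under salt stress (YPD + 1.2 M NaCl).
# anova_p compares mean w between the two media at each transfer.
transfer	w_ypd	sem_ypd	n_ypd	w_nacl	sem_nacl	n_nacl	anova_p
0	0.99	0.02	10	0.95	0.01	10	0.1417
7	0.98	0.02	12	1.01	0.02	12	0.3806
10	0.99	0.01	16	1.16	0.04	16	0.0031
16	0.96	0.03	6	0.90	0.06	6	0.3905
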