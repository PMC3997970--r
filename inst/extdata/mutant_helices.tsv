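# Alpha-helical residues (one-letter codes, positions -1 to 9 of the
# recognition helix collapsed to a 9-character string) of the SP1 second
# finger and the five mutants. substituted_positions lists the 1-based
# positions marked as exchanged in the source (metadata only; no
# residue-to-triplet model is implied).
name	residues	substituted_positions
SP1	RSDELKRHK	
CB1	HSSRLIRHE	1,4,6,9
MR14	RSSTLIQHK	4,7
MQ91	QSSYLIKHK	1,4,7
MQ135	QSSHLIQHK	1,4,7
MQ151	QSSYLTQHK	1,4,7
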