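allele	sub_allele	variants	structural_event	source_gene
*1				GENEA
*2		100:A>G;200:C>T		GENEA
*4	.001	100:A>G		GENEA
*5			gene_deletion	GENEA
*68			hybrid:600-1000	GENEA
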