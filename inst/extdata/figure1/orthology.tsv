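species_a	gene_a	species_b	gene_b
A	g1	B	g6
A	g2	B	g7
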