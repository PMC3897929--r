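protein_a	protein_b	score
p1_1	p4_1	900
p1_2	p5_1	800
p3_1	p5_2	700
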