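species	gene_id	gene_name	chromosome	start	end	strand	transcript_id	protein_id
A	g1	gene one	chr1	100	200	1	t1_1	p1_1
A	g1	gene one	chr1	100	200	1	t1_2	p1_2
A	g2	gene two	chr1	300	400	-1	t2_1	p2_1
A	g3	gene three	chr1	500	600	1	t3_1	p3_1
A	g4	gene four	chr1	700	800	1	t4_1	p4_1
A	g5	gene five	chr1	900	1000	-1	t5_1	p5_1
A	g5	gene five	chr1	900	1000	-1	t5_2	p5_2
B	g6	gene six	chr1	100	200	1	t6_1	p6_1
B	g7	gene seven	chr1	300	400	1	t7_1	p7_1
B	g8	gene eight	chr1	500	600	-1	t8_1	p8_1
B	g9	gene nine	chr1	700	800	1	t9_1	p9_1
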