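# worked-example replay script: one action per line, tab-separated
container	I	A
snapshot	a	I	-
add	a	gene	g1,g2,g3
snapshot	b	I	a
add	b	protein	p1_1,p4_1
add	b	transcript	t1_2,t2_1
minus	b	gene	g3
snapshot	c	I	a
extend	c
snapshot	d	I	c
network_add	d	c	1
container	II	B
snapshot	e	II	-
translate_add	e	d
snapshot	f	II	e
add	f	gene	g8,g9
minus	f	gene	g7
snapshot	g	I	-
translate_add	g	f
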