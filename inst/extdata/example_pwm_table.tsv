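motif_id	base	p1	p2	p3	p4
UP00001	A	0.1	0.7	0.1	0.2
UP00001	C	0.2	0.1	0.1	0.2
UP00001	G	0.3	0.1	0.7	0.3
UP00001	T	0.4	0.1	0.1	0.3
UP00002	A	12	0	3	1
UP00002	C	0	14	3	1
UP00002	G	2	0	5	11
UP00002	T	0	0	3	1
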