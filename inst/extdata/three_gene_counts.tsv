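gene_id	condition	record	count	rate_1	rate_2
g1	c1	category	200	250	250
g1	c1	category	150	55	0
g1	c1	category	5	0	25
g1	c1	totals	355	310	280
g1	c2	category	210	250	250
g1	c2	category	6	55	0
g1	c2	category	140	0	25
g1	c2	totals	356	310	280
g2	c1	category	100	225	NA
g2	c1	totals	100	225	NA
g2	c2	category	300	225	NA
g2	c2	totals	300	225	NA
g3	c1	category	2	80	40
g3	c1	totals	2	120	60
g3	c2	category	3	80	40
g3	c2	totals	3	120	60
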