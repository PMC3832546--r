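exon_id	condition	UJC	DJC	SJC
e1	treated	30	30	20
e1	control	10	10	30
e2	treated	25	35	0
e2	control	30	30	30
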