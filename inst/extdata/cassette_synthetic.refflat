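simgene	isoA	chr1	+	0	3600	0	0	3	0,2000,3000,	1200,2060,3600,
simgene	isoB	chr1	+	0	3600	0	0	2	0,3000,	1200,3600,
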