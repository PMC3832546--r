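chr1	demo	exon	1	300	.	+	.	gene_id "g1"; transcript_id "g1a";
chr1	demo	exon	401	460	.	+	.	gene_id "g1"; transcript_id "g1a";
chr1	demo	exon	501	800	.	+	.	gene_id "g1"; transcript_id "g1a";
chr1	demo	exon	1	300	.	+	.	gene_id "g1"; transcript_id "g1b";
chr1	demo	exon	501	800	.	+	.	gene_id "g1"; transcript_id "g1b";
chr1	demo	exon	2001	2500	.	-	.	gene_id "g2"; transcript_id "g2a";
chr2	demo	exon	1	200	.	+	.	gene_id "g3"; transcript_id "g3a";
chr2	demo	exon	301	500	.	+	.	gene_id "g3"; transcript_id "g3a";
chr2	demo	exon	301	500	.	+	.	gene_id "g3"; transcript_id "g3b";
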