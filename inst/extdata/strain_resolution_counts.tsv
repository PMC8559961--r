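data	metric	sp	ckr	both
RNA-seq	Differential expression	1095	456	366
RNA-seq	Overexpressed CYPs	22	15	14
RNA-seq	Homozygous SNPs	60527	34665	14350
Proteomics	Differential expression	286	139	57
Proteomics	Overexpressed CYPs	28	16	16
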