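study	platform	n_external_cnvr	n_overlapped	printed_ratio_pct
cgh_a	CGH	31	1	0.00
cgh_b	CGH	241	47	1.33
cgh_c	CGH	48	8	0.22
cgh_d	CGH	602	129	3.65
snp60_a	SNP60	47	104	2.94
snp60_b	SNP60	537	262	7.41
snp60_c	SNP60	357	130	3.67
snp60_d	SNP60	234	670	18.94
snp60_e	SNP60	166	100	2.83
snp60_f	SNP60	480	579	16.37
snp60_g	SNP60	3746	182	5.14
snp60_h	SNP60	166	84	2.37
snp60_i	SNP60	256	189	5.34
infinium_a	InfiniumII	57	20	0.57
ngs_a	NGS	2880	70	1.98
ngs_b	NGS	2820	238	6.73
ngs_c	NGS	1238	33	0.93
ngs_d	NGS	2359	53	1.50
ngs_e	NGS	433	13	0.37
ngs_f	NGS	508	153	4.32
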