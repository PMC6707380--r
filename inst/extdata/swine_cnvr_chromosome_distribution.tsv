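chrom	length	n_cnvr	unique_bp	printed_ratio_pct
SSC1	274330532	1231	7969003	2.90
SSC2	151935994	192	1318835	0.87
SSC3	132848913	101	570813	0.43
SSC4	130910915	137	523004	0.40
SSC5	104526007	146	1132811	1.08
SSC6	170843587	152	772899	0.45
SSC7	121844099	141	638302	0.52
SSC8	138966237	203	1599178	1.15
SSC9	139512083	167	1088850	0.78
SSC10	69359453	82	407652	0.59
SSC11	79169978	103	1338230	1.69
SSC12	61602749	52	337802	0.55
SSC13	208334590	231	1636688	0.79
SSC14	141755446	126	1099698	0.78
SSC15	140412725	141	734861	0.52
SSC16	79944280	127	449040	0.56
SSC17	63494081	62	277525	0.44
SSC18	55982971	49	433245	0.77
SSCX	125939595	93	582165	0.46
SSCY	43547828	2	17943	0.04
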