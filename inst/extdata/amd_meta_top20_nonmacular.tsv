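# Published top-20 meta-gene table, AMD vs control non-macular RPE/choroid
# (microarray + RNAseq Fisher meta-analysis). Same conventions as the
# macular table.
entrez	symbol	F_g	p_printed	effect
54108	CHRAC1	-40.355	0.00066	Up-regulated
10648	SCGB1D1	-36.412	0.00216	Up-regulated
64116	SLC39A8	-31.469	0.00826	Up-regulated
84656	GLYR1	-30.629	0.00826	Up-regulated
79095	C9orf16	-30.731	0.00826	Up-regulated
6422	SFRP1	-28.224	0.01414	Up-regulated
1974	EIF4A2	32.756	0.0081	Down-regulated
58155	PTBP2	30.667	0.00826	Down-regulated
400073	C12orf76	31.225	0.00826	Down-regulated
146225	CMTM2	29.187	0.0118	Down-regulated
65982	ZSCAN18	29.314	0.0118	Down-regulated
23564	DDAH2	29.244	0.0118	Down-regulated
115761	ARL11	28.924	0.01223	Down-regulated
6404	SELPLG	27.816	0.01414	Down-regulated
84695	LOXL3	27.903	0.01414	Down-regulated
8936	WASF1	27.635	0.01414	Down-regulated
8675	STX16	27.52	0.01414	Down-regulated
8803	SUCLA2	27.535	0.01414	Down-regulated
54816	ZNF280D	28.257	0.01414	Down-regulated
3187	HNRNPH1	27.798	0.01414	Down-regulated
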