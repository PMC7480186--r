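# Published top-20 meta-gene table, AMD vs control macular RPE/choroid
# (microarray + RNAseq Fisher meta-analysis). F_g is signed: negative for
# up-regulated genes, positive for down-regulated. p_printed is the
# BH-adjusted combined p-value exactly as printed.
entrez	symbol	F_g	p_printed	effect
84624	FNDC1	-47.991	1.72E-05	Up-regulated
4060	LUM	-46.502	1.75E-05	Up-regulated
131578	LRRC15	-40.042	0.00019	Up-regulated
5803	PTPRZ1	-38.086	0.00032	Up-regulated
9547	CXCL14	-38.22	0.00032	Up-regulated
8148	TAF15	-35.072	0.00102	Up-regulated
4804	NGFR	-34.669	0.00109	Up-regulated
3381	IBSP	-31.756	0.00272	Up-regulated
3371	TNC	-31.912	0.00272	Up-regulated
1118	CHIT1	-31.852	0.00272	Up-regulated
1515	CTSV	-31.612	0.00272	Up-regulated
84466	MEGF10	-31.106	0.00278	Up-regulated
2224	FDPS	-31.247	0.00278	Up-regulated
6695	SPOCK1	-30.827	0.00287	Up-regulated
55827	DCAF6	40.05	0.00019	Down-regulated
64093	SMOC1	37.387	0.00039	Down-regulated
7066	THPO	31.517	0.00272	Down-regulated
100128731	OST4	31.747	0.00272	Down-regulated
2619	GAS1	32.158	0.00272	Down-regulated
83473	KATNAL2	31.124	0.00278	Down-regulated
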