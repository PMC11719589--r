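snp_id	chrom	pos	counted_allele	other_allele	maf_reference	gene
rs1281744	1	116411750	C	T	0.1127	SLC22A15
rs11123610	2	3700901	C	T	0.3783	ALLC
rs295137	2	200858285	T	C	0.3431	SPATS2L
rs901865	3	11275707	A	G	0.1526	HRH1
rs892940	3	24513842	T	C	0.4393	THRB
rs10044254	5	15836596	C	T	0.2615	FBXL7
rs13182402	5	125918148	G	A	0.1035	ALDH7A1
rs41423247	5	142778575	G	C	0.3504	NR3C1
rs1042713	5	148206440	A	G	0.4093	ADRB2
rs2067474	5	175041825	A	G	0.0381	HRH2
rs730012	5	179153244	C	A	0.2449	LTC4S
rs2395672	6	37428577	A	G	0.2071	CMTR1
rs2781667	6	131895144	T	C	0.3316	ARG1
rs2305089	6	166499260	T	C	0.4532	TFT
rs37973	7	800787	C	T	0.4673	GLCCI1
rs2190242	7	30709475	C	A	0.3570	CRHR2
rs2691529	7	77641211	C	T	0.2691	MAGI2
rs1049793	7	150557665	G	C	0.3477	AOC1
rs2115819	10	45221095	C	T	0.4796	ALOX5
rs11000016	10	73579217	T	C	0.1592	PSAP
rs2660845	12	94962684	G	A	0.2881	LTA4
rs7140310	14	6811073	C	A	0.1516	ARG2
rs3742879	14	67184754	G	A	0.2967	ARG2
rs17525472	15	49756960	C	T	0.1292	SCG3
rs2230739	16	3973437	C	T	0.3460	ADCY9
rs11665084	18	20310764	T	C	0.1220	HRH4
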