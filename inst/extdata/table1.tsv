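sample	material	vaf_pct	gene	chrom	arm	base_change	protein_change	consequence	cosmic_id	sift_call	sift_score	polyphen_call	polyphen_score	revel_score
ctD4	ctDNA_blood	2.85	ALK	chr2	p23.2	c.(3824G>A)	p.(R1275Q)	missense	COSV66555567	Del	0	PRD	1	0.885
ctD4	ctDNA_blood	28.5	ALK	chr2	p23.2	c.(3522C>A)	p.(F1174L)	missense	COSV66556325	Del	0.03	POD	0.641	0.752
ctD10	ctDNA_blood	1.38	ALK	chr2	p23.2	c.(3509T>A)	p.(I1170N)	missense	COSV66589132	Del	0	PRD	1	0.906
ctD10	ctDNA_blood	26.16	KRAS	chr12	p12.1	c.(35G>T)	p.(G12V)	missense	COSV55497419	Del	0	PRD	0.972	0.91
ctD10	ctDNA_blood	3.61	PTPN11	chr12	q24.13	c.(179G>C)	p.(G60A)	missense	COSV61006397	Del	0.01	PRD	0.953	0.907
ctD11	ctDNA_blood	84.88	TP53	chr17	p13.1	c.(537T>A)	p.(H179G)	missense	COSV52673406	Del	0	PRD	0.98	0.79
gD1	germline	1.4	TP53	chr17	p13.1	c.(537T>A)	p.(H179Q)	missense	COSV52669519	Del	0	PRD	0.98	0.79
ctD13	ctDNA_blood	3.33	ALK	chr2	p23.2	c.(3522C>A)	p.(F1174L)	missense	COSV66556325	Del	0.03	POD	0.641	0.752
ctD15	ctDNA_blood	35.8	PTPN11	chr12	q24.13	c.(922A>G)	p.(N308D)	missense	COSV61006575	Del	0.03	B	0.134	0.838
gD2	germline	43.9	PTPN11	chr12	q24.13	c.(922A>G)	p.(N308D)	missense	COSV61006575	Del	0.03	B	0.134	0.838
ctD16	ctDNA_blood	4.34	PTPN11	chr12	q24.13	c.(181G>T)	p.(D61Y)	missense	COSV61004841	Del	0	PRD	0.997	0.933
ctD17	ctDNA_blood	2.26	NRAS	chr1	p13.2	c.(181C>A)	p.(Q61K)	missense	COSV54736310	Del	0.01	POD	0.709	N/A
ctD20	ctDNA_blood	91.64	TP53	chr17	p13.1	c.(840A>T)	p.(R280S)	missense	COSV52782181	Del	0.03	POD	0.843	0.878
ctD21	ctDNA_blood	83.4	TP53	chr17	p13.1	c.(840A>T)	p.(R280S)	missense	COSV52801834	Del	0.03	POD	0.843	0.878
ctD22	ctDNA_blood	29.03	ALK	chr2	p23.2	c.(3824G>A)	p.(R1275Q)	missense	COSV66555567	Del	0	PRD	1	0.885
ctD25	ctDNA_blood	18.7	PTPN11	chr12	q24.13	c.(226G>C)	p.(E76Q)	missense	COSV61004751	Del	0.01	PRD	0.979	0.733
ctD28	ctDNA_blood	2.2	CREBBP	chr16	p13.3	c.(4478T>A)	p.(I1493K)	missense	COSV52129182	Del	0	PRD	0.991	0.929
SHSY5Y	cell_line	44.4	KRAS	chr12	p12.1	c.(35G>T)	p.(G12V)	missense	COSV55497419	Del	0	PRD	0.972	0.91
SHSY5Y	cell_line	50.9	SMARCA4	chr19	p13.2	c.(2917C>T)	p.(R973W)	missense	COSV60787034	Del	0	PRD	1	0.86
SHSY5Y	cell_line	49.6	ALK	chr2	p23.2	c.(3522C>A)	p.(F1174L)	missense	COSV66555460	Del	0.03	POD	0.641	0.752
SKNBE2C	cell_line	99.1	TP53	chr17	p13.1	c.(404G>T)	p.(C135F)	missense	COSV52680475	Del	0	PRD	1	0.96
SKNBE2C	cell_line	100	NF1	chr17	q11.2	c.(1989_2001del)	p.(G663fs)	splice_donor	N/A	N/A	N/A	N/A	N/A	N/A
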