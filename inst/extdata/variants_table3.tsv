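patient_id	chrom	pos	ref	alt	gene	hgvs_p	consequence	score	in_splice_site	db_excluded	allele_count	allele_number
112940	9	32989766	G	A	APTX	p.R56X	stop_gain	NA	FALSE	FALSE	0	66736
112940	17	41246481	T	C	BRCA1	p.Q356R	missense	4	FALSE	FALSE	4198	66734
112940	4	178274801	T	G	NEIL3	p.F460C	missense	3	FALSE	FALSE	10	66730
117197	22	43933284	CCT	C	EFCAB6	p.Q1340Rfs*43	frameshift	NA	FALSE	FALSE	606	66684
117197	2	38301879	T	A	CYP1B1	p.D218V	missense	5	FALSE	FALSE	15	41314
117197	10	89503283	C	T	PAPSS2	p.P454L	missense	5	FALSE	FALSE	0	66732
117197	17	41246481	T	C	BRCA1	p.Q356R	missense	4	FALSE	FALSE	4198	66734
117197	9	135779052	G	A	TSC1	p.H732Y	missense	4	FALSE	FALSE	350	66706
117939	1	156212872	T	A	BGLAP	p.C74X	stop_gain	NA	FALSE	FALSE	8	66696
117939	2	58386928	G	GTAAT	FANCL	p.T367Nfs*13	frameshift	NA	FALSE	FALSE	232	65648
117939	5	80109533	T	C	MSH3	p.I929T	missense	5	FALSE	FALSE	0	66740
117939	12	124209215	G	T	ATP6V0A2	p.K103N	missense	5	FALSE	FALSE	15	66734
117939	3	51673972	A	T	RAD54L2	p.I730F	missense	4	FALSE	FALSE	NA	NA
117939	21	16340242	T	C	NRIP1	p.E91G	missense	4	FALSE	FALSE	NA	NA
117939	2	149226489	C	T	MBD5	p.A326V	missense	3	FALSE	FALSE	NA	NA
123136	4	1206089	G	A	CTBP1	p.P421L	missense	4	FALSE	FALSE	28	14670
123136	3	38888684	A	T	SCN11A	p.F1626Y	missense	3	FALSE	FALSE	NA	NA
123136	1	63876815	A	G	ALG6	Splice acceptor (-2)	splice	NA	FALSE	FALSE	NA	NA
123136	1	120056817	T	TGCA	HSD3B1	p.V224_Y225insH	inframe_indel	NA	FALSE	FALSE	2	66708
123136	4	153332604	TCTC	T	FBXW7	p.E117del	inframe_indel	NA	FALSE	FALSE	35	66114
124604	16	23634293	C	T	PALB2	p.G998E	missense	5	FALSE	FALSE	1430	66736
124604	16	89815152	G	A	FANCA	p.S1088F	missense	4	FALSE	FALSE	4798	65430
124604	15	91326099	C	T	BLM	p.P868L	missense	4	FALSE	FALSE	4239	66162
124604	6	49700908	G	A	CRISP3	p.A197V	missense	2	TRUE	FALSE	0	66362
124853	18	3452067	G	A	TGIF1	p.W30X	stop_gain	NA	FALSE	FALSE	33	66002
124853	4	55955969	C	T	KDR	p.A1065T	missense	5	TRUE	FALSE	52	66726
124853	17	12901781	A	C	ELAC2	p.S490A	missense	5	FALSE	FALSE	39	66734
124853	19	50766628	C	T	MYH14	p.A882V	missense	3	FALSE	FALSE	23	27644
124853	X	110973633	TGAA	T	ALG13	p.E795del	inframe_indel	NA	FALSE	FALSE	33	41558
124853	4	103747794	C	T	UBE2D3	Splice acceptor (-1)	splice	NA	FALSE	FALSE	NA	NA
125671	9	35707745	G	C	TLN1	p.L1539V	missense	4	FALSE	FALSE	13	66734
125671	1	145578236	C	T	PIAS3	p.R67W	missense	3	FALSE	FALSE	13	66740
125671	10	5014483	T	A	AKR1C1	p.S221N	missense	3	FALSE	FALSE	119	66712
125671	10	5014484	C	A	AKR1C1	p.S221N	missense	NA	FALSE	FALSE	119	66712
125671	11	47237894	CAGA	C	DDB2	p.R47del	inframe_indel	NA	FALSE	FALSE	NA	NA
126002	17	35564593	G	A	ACACA	p.R1182W	missense	5	FALSE	FALSE	16	66612
126002	17	41246481	T	C	BRCA1	p.Q356R	missense	4	FALSE	FALSE	4198	66734
126002	7	18633593	A	G	HDAC9	p.Y199C	missense	3	FALSE	FALSE	0	66702
129413	14	50088465	T	G	MGAT2	p.I160S	missense	5	FALSE	FALSE	610	66402
129413	17	41246481	T	C	BRCA1	p.Q356R	missense	4	FALSE	FALSE	4198	66734
129413	15	43762077	TGGGATA	T	TP53BP1	p.I455_P456del	inframe_indel	NA	FALSE	FALSE	NA	NA
129547	2	38298287	T	TGGTGGCATCA	CYP1B1	p.T404Sfs*30	frameshift	NA	FALSE	TRUE	NA	NA
129547	10	94297192	C	T	IDE	p.G72S	missense	5	FALSE	FALSE	8	66724
129547	12	124824917	C	T	NCOR2	p.R1794Q	missense	3	FALSE	FALSE	2	65378
129547	21	16337279	C	A	NRIP1	p.V1079F	missense	3	FALSE	FALSE	44	66670
129748	16	23632788	TTTTC	T	PALB2	p.E1002Tfs*4	frameshift	NA	FALSE	FALSE	NA	NA
129748	6	52657698	C	T	GSTA1	p.E168K	missense	4	FALSE	FALSE	1	66738
129748	8	48973252	G	A	UBE2V2	p.R101Q	missense	4	FALSE	FALSE	1	65850
129748	20	31021718	C	T	ASXL1	p.R573W	missense	4	TRUE	FALSE	4	63434
129748	12	53776449	G	C	SP1	p.G240R	missense	3	FALSE	FALSE	26	66738
129748	11	62388048	G	C	B3GAT3	p.R60G	missense	3	FALSE	FALSE	1	60290
131534	9	131709581	A	AT	DOLK	p.M1?	start_loss	NA	FALSE	FALSE	823	63350
131534	13	28592620	T	C	FLT3	p.Y842C	missense	5	FALSE	FALSE	2	66710
131534	10	94274700	A	G	IDE	p.M254T	missense	5	FALSE	FALSE	11	66698
131534	4	70723282	C	G	SULT1E1	p.W27C	missense	4	FALSE	FALSE	NA	NA
131534	1	120478125	A	C	NOTCH2	p.F1209V	missense	4	FALSE	FALSE	306	66726
131534	17	33430313	T	C	RAD51D	p.E223G	missense	4	FALSE	FALSE	874	51128
131534	1	182555767	C	T	RNASEL	p.G59S	missense	4	FALSE	FALSE	379	66514
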