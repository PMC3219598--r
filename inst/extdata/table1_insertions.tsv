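# Machine-readable transcription of the published per-case insertion list
# (18 L1 EN-mediated de novo insertions in NF1). Coordinates are transcript
# (c.) positions; intronic offsets use +/- notation. dup_* give the printed
# target-site duplication; del_* a target-site deletion replacing the TSD.
# truncation = missing 5' bases of the element body versus the bundled
# consensus (NA = not applicable / unknown); polyA_len is the fixture tail
# length (100 where the source gives no estimate). tsd_expected is the
# maximal duplicated flank measurable from the sequences themselves; it
# exceeds tsd_printed by 1 for two cases where the reference base 5' of the
# TSD coincides with the complement of the element head (see notes).
# products: transcript-level outcomes, one per product, ';'-separated,
# each "lostStart:lostEnd[:gainedElementNt]".
case_id	row	location	region	element_printed	family	l1_subset	size_printed	truncation	truncation_expected	inverted	orientation	polyA_printed	polyA_len	c_name_printed	dup_start	dup_end	dup_seq	del_start	del_end	nt5	tsd_printed	tsd_expected	tail_expected	junction_shift	r_printed	frame_printed	splice_type_printed	products	notes
UAB-R10408	1	IVS 14 (10c)	intronic	AluY	AluY	NA	280/N	0	0	no	S	no estimate	100	c.1642-1_1642insAluY,1642-11_1642-1dupAAAAAATTCAG	1642-11	1642-1	AAAAAATTCAG	NA	NA	NA	11	11	100	0	r.1642_1721del	IF	1	1642:1721	printed frame IF but the 80-nt skip is not divisible by 3; computed OOF
UAB-R119201	2	IVS 10 (8)	intronic	AluY	AluY	NA	281/N	0	0	no	AS	no estimate	100	c.1186-86_1186-16delinsAluY	NA	NA	NA	1186-86	1186-16	NA	0	0	100	0	r.1186_1260del	IF	1	1186:1260	71-bp target-site deletion with no TSD; nick position tentative
MUI-1	3	E6 (4c)	exonic	AluYa5	AluYa5	NA	282/N	0	0	no	S	~60 bp	60	c.650_651dupinsAluYa5,637_650dupATAAATAGCCTGGA	637	650	ATAAATAGCCTGGA	NA	NA	NA	14	14	60	0	r.587_654del	IF	2	587:654	printed frame IF but the 68-nt skip is not divisible by 3; computed OOF
UAB-R37305	4	E21 (16)	exonic	AluYa5	AluYa5	NA	284/N	0	1	no	AS	120 bp	120	c.2835_2836insAluYa5,2824_2835dupAGCAAGTTTTTT	2824	2835	AGCAAGTTTTTT	NA	NA	NA	12	13	120	0	r.2618_2850del	NA	3	2618:2850	reference base at c.2823 (fixed by the second exon 21 case) equals the complement of the Alu head, so the maximal duplicated flank is 13; the coincident base also registers as a 1-bp 5-prime truncation of the measured body
UAB-R37616	5	E21 (16)	exonic	AluYa5	AluYa5	NA	281/N	0	0	no	AS	no estimate	100	c.2835_2836insAluYa5,2819_2835dupCCATCAGCAAGTTTTTT	2819	2835	CCATCAGCAAGTTTTTT	NA	NA	NA	17	17	100	0	r.2618_2850del	NA	3	2618:2850	NA
UAB-R30609	6	E22 (17)	exonic	AluYa5	AluYa5	NA	284/N	0	0	no	AS	110 bp	110	c.2858_2859insAluYa5,2851-7_2858dupTCTTTAGGTTTTA	2851-5	2858	TCTTTAGGTTTTA	NA	NA	NA	13	15	108	2	r.2851_2990del	OOF	2	2851:2990	printed dup span 2851-7_2858 covers 15 positions for a 13-nt string; under the maximal-duplication convention the measured flank is 15 bp (two downstream T nucleotides join the duplication) with the junction 2 bp 3-prime of the printed point
UAB-R81017	7	E33 (25)	exonic	AluYa5	AluYa5	NA	279/N	0	0	no	S	no estimate	100	c.4319_4320insAluYa5,4305_4319dupAAAAGAAGAACATAT	4305	4319	AAAAGAAGAACATAT	NA	NA	NA	15	15	100	0	r.4270_4367del	OOF	2	4270:4367	NA
MUI-2	8	E47 (38)	exonic	AluYa5	AluYa5	NA	264/Y	17	17	no	AS	60-85 bp	70	c.6951_6952insAluYa5,6936_6951dupAGGTACCGCACTTCTT	6936	6951	AGGTACCGCACTTCTT	NA	NA	NA	16	16	70	0	r.[6859_6999del;6938_6999del]	IF	2&3	6859:6999;6938:6999	two transcript products
UAB-R869001	9	E12 (10a)	exonic	AluYb8	AluYb8	NA	249/Y	39	39	no	S	121 bp	121	c.1354_1355insAluYb8,1345_1354dupAAAGCAGTGC	1345	1354	AAAGCAGTGC	NA	NA	NA	10	10	121	0	r.1355_1392delins61	NA	5	1355:1392:61	cryptic 5' splice site inside the truncated element; first 61 element nt retained
UAB-R164201	10	IVS 14 (10c)	intronic	AluYb8	AluYb8	NA	288/N	0	0	no	AS	no estimate	100	c.1642-12_1642-11insAluYb8,1642-28_1642-12dupTTGTCTTTCTCTTTTTT	1642-28	1642-12	TTGTCTTTCTCTTTTTT	NA	NA	NA	17	17	100	0	r.1642_1721del80	OOF	1	1642:1721	7 nt printed upstream of the TSD equal the reverse complement of the Alu head and are treated as mutant-allele read-through, not reference
UAB-R39428	11	E21 (16)	exonic	AluYb8	AluYb8	NA	289/N	0	1	no	AS	120 bp	120	c.2439_2440insAluYb8,2428_2439dupAAGACCATTGTT	2428	2439	AAGACCATTGTT	NA	NA	NA	12	13	120	0	r.2410_2638del	NA	4	2410:2638	reference base at c.2427 in the printed window equals the complement of the Alu head, so the maximal duplicated flank is 13; the coincident base also registers as a 1-bp 5-prime truncation of the measured body
UAB-R50109	12	E22 (17)	exonic	AluYb8	AluYb8	NA	288/N	0	0	no	S	78-178 bp	120	c.2979_2980insAluYb8,2966_2979dupAAACAATGATGTTA	2966	2979	AAACAATGATGTTA	NA	NA	NA	14	14	120	0	r.2851_2990del	OOF	2	2851:2990	NA
UAB-R340101	13	E33 (25)	exonic	AluYb8	AluYb8	NA	288/N	0	0	no	S	118 bp	118	c.4319_4320insAluYb8,4305_4319dupAAAAGAAGAACATAT	4305	4319	AAAAGAAGAACATAT	NA	NA	NA	15	15	118	0	r.4270_4367del	OOF	2	4270:4367	same integration site and TSD as the other exon 33 case
UAB-R07118	14	IVS 48 (39)	intronic	AluYb8	AluYb8	NA	268/Y	20	20	no	AS	121 bp	121	c.7127-5_7127-4insAluYb8,7127-20_7127-5dupTGTTTGTTTGTTTTTT	7127-20	7127-5	TGTTTGTTTGTTTTTT	NA	NA	NA	16	16	121	0	r.7127_7258del	IF	1	7127:7258	NA
UAB-R75103	15	E25 (19b)	exonic	poly(T) strech	polyN	NA	~130/Y	NA	NA	no	AS	120 bp	120	c.3312_3313insT(n~120),3307_3312dupTTTCTT	3307	3312	TTTCTT	NA	NA	NA	6	6	120	0	r.3275_3314del	NA	3	3275:3314	pure poly(T) insert; no element body
UAB-R316001	16	E23 (18)	exonic	L1(preTa)	L1	preTa	~1800/Y	4063	4063	no	S	no estimate	100	c.3048_3049insTGTGAATTinsL1(Ta)_0rf2,3033_3048dupAAAAACGAAACTGTGT	3033	3048	AAAAACGAAACTGTGT	NA	NA	TGTGAATT	16	16	100	0	r.2991_3113del	IF	2	2991:3113	printed element token carries a digit-zero typo (0rf2); running text assigns the pre-Ta subset; 8-nt non-templated 5' addition
UAB-R01429	17	E39 (30)	exonic	L1(Ta)	L1	Ta	~6000/N	0	0	no	S	no estimate	100	c.5606_5607insL1,5594_5606dupTAAAAATCGAGGG	5594	5606	TAAAAATCGAGGG	NA	NA	NA	13	13	100	0	r.5607_5749delins96	NA	5	5607:5749:96	full-length element; cryptic 5' splice site in the element retains its first 96 nt
UAB-R91409	18	IVS 9 (7)	intronic	n.k.	L1	NA	~2200/Y	NA	NA	yes	AS	no estimate	100	c.1062+195_1062+196insL1,1062+185_1062+195dupTTCTTTTACCA	1062+185	1062+195	TTCTTTTACCA	NA	NA	NA	11	11	100	0	r.889_1062delins130	OOF	6	889:1062:130	5'-inverted L1 (twin priming) with 2-bp junction microhomology; 130-nt element-derived cryptic exon
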