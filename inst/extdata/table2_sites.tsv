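# Machine-readable transcription of the published integration-site windows,
# aligned to the L1 endonuclease cleavage consensus (3'-AA/TTTT-5'). Each
# printed_window is the 36-nt sequence as printed on the nicked strand read
# 3'->5' (the space at the nick removed). conversion maps it onto the
# top-strand fixture frame: "complement" for sense-oriented inserts (bottom
# strand nicked), "reverse" for antisense inserts (top strand nicked);
# "as_is" for the intron 9 row, which matches its printed dup string only
# when read directly as top-strand 5'->3'. window_trim5 = number of
# genomically-upstream window bases discarded as mutant-allele read-through
# (nonzero only for the intron 14 antisense case, where 7 bases equal the
# reverse complement of the Alu 5' head). The printed table merges the final
# two entries (TSD column "116"); they are split here as 11 and 6.
case_id	printed_window	conversion	window_trim5	tsd_printed	strand_printed	family_printed	location_printed
UAB-R10408	AAAGAGAAAAAATTTTTTAAGTCCGAGACGACCAAG	complement	0	11	sense	Y	I 14 (10c)
UAB-R119201	TTGTCGTTTATCTTTCAAATTTTTTTGTGATTCAAA	reverse	0	NA	antisense	Y	I 10 (8)
MUI-1	GTCAATCGTCAATATTTATCGGACCTTTTCCATTCA	complement	0	14	sense	Ya5	E 6 (4c)
UAB-R37305	AGGAACCCTCAGTTTTTTGAACGACTACCATAAGAA	reverse	0	12	antisense	Ya5	E 21 (16)
UAB-R37616	AGGAACCCTCAGTTTTTTGAACGACTACCATAAGAA	reverse	0	17	antisense	Ya5	E 21 (16)
UAB-R30609	CCATAGTCAGTTATTTTGGATTTCTTTCTTGTTTAT	reverse	0	13	antisense	Ya5	E 22 (17)
UAB-R81017	ACAAGAGAAGTGTTTTCTTCTTGTATACGCCGGAAA	complement	0	15	sense	Ya5	E 33 (25)
MUI-2	GTCCAAAACAAGTTCTTCACGCCATGGACGACTTAT	reverse	0	16	antisense	Ya5	E 47 (38)
UAB-R869001	CTTTGTGAAGTATTTCGTCACGTTCCAACACCTCGT	complement	0	10	sense	Yb8	E 12 (10a)
UAB-R164201	GGACTTAAAAAATTTTTTCTCTTTCTGTTCCGGCCC	reverse	7	17	antisense	Yb8	I 14 (10c)
UAB-R39428	GTAAGCGGAGAATTGTTACCAGAACACTTCCGAAAG	reverse	0	12	antisense	Yb8	E 21 (16)
UAB-R50109	TTCGATCGTAACTTTGTTACTACAATTTAGACCAGT	complement	0	14	sense	Yb8	E 22 (17)
UAB-R340101	ACAAGAGAAGTGTTTTCTTCTTGTATACGCCGGAAA	complement	0	15	sense	Yb8	E 33 (25)
UAB-R07118	GGACATGGGATGTTTTTTGTTTGTTTGTTTGTTTGT	reverse	0	16	antisense	Yb8	I 48 (39)
UAB-R316001	ACGTTAAGTTTATTTTTGCTTTGACACAGTTAATCA	complement	0	16	sense	L1P1_orf2	E 23 (18)
UAB-R01429	CATGGAAATTAAATTTTTAGCTCCCGGTCAATGATC	complement	0	13	sense	LINE 1	E 39 (30)
UAB-R91409	AATACGAATAAATTCTTTTACCAAGTAACATCTAAG	as_is	0	11	antisense	L1	I 9 (7)
UAB-R75103	ACTTTAAATGAATTCTTTATTGACACTAAACCGAAG	reverse	0	6	antisense	T(n~120)	E 25 (19b)
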