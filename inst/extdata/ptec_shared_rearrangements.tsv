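set_id	v_call	n1_seq	d_call	n2_seq	j_call	cells
1	IGHV1-24	TT	IGHD2-15	ACCCGATCCGAC	IGHJ4	1-3,1-6,1-15,1-19,1-21,1-29,1-39,2-10,2-11,2-18,2-30,2-42,2-45
2	IGHV1-18	TCTTAGTGGTTC	IGHD3-9		IGHJ6	1-16,1-32,1-41,2-16
3	IGHV1-2	TCGGGGGG	IGHD3-3	CTTGGAGCCT	IGHJ6	1-8,2-37
4	IGHV1-2	CTCTAT	IGHD3-9	AGCTGACA	IGHJ5	1-45,2-38
5	IGHV1-3	CTTACC	IGHD3-22	GGATC	IGHJ4	1-17,2-43
6	IGHV1-69	TCTGCCATTG	IGHD5-12	ATCCCCG	IGHJ4	1-23,2-14
7	IGHV1-69	CCCTAAAG	IGHD2-15	GTTCTTTCTTGACGGCCC	IGHJ4	1-20,2-44
8	IGHV1-8	CAACCGGGGCCAGCATACTG	IGHD3-3	CCTATGG	IGHJ5	1-24,2-12
9	IGHV3-23	TAAATCAATCGATAT	IGHD3-3	GTTACGGA	IGHJ3	1-22,2-26
10	IGHV4-59	TCGTTCA	IGHD3-22	CCGGAGTTTTTACCC	IGHJ3	1-43,2-2
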