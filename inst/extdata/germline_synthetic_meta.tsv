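name	segment_class	family	genomic_order_index	fr1_start	cdr1_start	fr2_start	cdr2_start	fr3_start	cdr3_anchor	j_trp_anchor
IGHV6-1	V	VH6	0	0	75	99	150	174	288	
IGHV1-2	V	VH1	1	0	75	99	150	174	288	
IGHV1-3	V	VH1	2	0	75	99	150	174	288	
IGHV7-4-1	V	VH7	3	0	75	99	150	174	288	
IGHV2-5	V	VH2	4	0	75	99	150	174	288	
IGHV3-7	V	VH3	5	0	75	99	150	174	288	
IGHV1-8	V	VH1	6	0	75	99	150	174	288	
IGHV3-9	V	VH3	7	0	75	99	150	174	288	
IGHV3-11	V	VH3	8	0	75	99	150	174	288	
IGHV3-15	V	VH3	9	0	75	99	150	174	288	
IGHV1-18	V	VH1	10	0	75	99	150	174	288	
IGHV3-21	V	VH3	11	0	75	99	150	174	288	
IGHV3-23	V	VH3	12	0	75	99	150	174	288	
IGHV1-24	V	VH1	13	0	75	99	150	174	288	
IGHV2-26	V	VH2	14	0	75	99	150	174	288	
IGHV3-30	V	VH3	15	0	75	99	150	174	288	
IGHV4-31	V	VH4	16	0	75	99	150	174	288	
IGHV3-33	V	VH3	17	0	75	99	150	174	288	
IGHV4-34	V	VH4	18	0	75	99	150	174	288	
IGHV4-39	V	VH4	19	0	75	99	150	174	288	
IGHV1-45	V	VH1	20	0	75	99	150	174	288	
IGHV1-46	V	VH1	21	0	75	99	150	174	288	
IGHV3-48	V	VH3	22	0	75	99	150	174	288	
IGHV5-51	V	VH5	23	0	75	99	150	174	288	
IGHV4-59	V	VH4	24	0	75	99	150	174	288	
IGHV4-61	V	VH4	25	0	75	99	150	174	288	
IGHV1-69	V	VH1	26	0	75	99	150	174	288	
IGHV2-70	V	VH2	27	0	75	99	150	174	288	
IGHD1-1	D	DH1	0							
IGHD2-2	D	DH2	1							
IGHD3-3	D	DH3	2							
IGHD4-4	D	DH4	3							
IGHD5-5	D	DH5	4							
IGHD6-6	D	DH6	5							
IGHD1-7	D	DH1	6							
IGHD3-9	D	DH3	7							
IGHD5-12	D	DH5	8							
IGHD2-15	D	DH2	9							
IGHD3-16	D	DH3	10							
IGHD3-22	D	DH3	11							
IGHD4-23	D	DH4	12							
IGHD1-26	D	DH1	13							
IGHD7-27	D	DH7	14							
IGHJ1	J	JH1	0							8
IGHJ2	J	JH2	1							10
IGHJ3	J	JH3	2							7
IGHJ4	J	JH4	3							9
IGHJ5	J	JH5	4							12
IGHJ6	J	JH6	5							13
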