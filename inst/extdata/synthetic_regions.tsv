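gene	scheme	fr1_start	cdr1_start	fr2_start	cdr2_start	fr3_start	fr3_end
IGHV1-S1*01	KABAT	0	90	105	165	195	294
IGHV1-S1*01	IMGT	0	75	99	150	174	294
IGHV1-S2*01	KABAT	0	93	108	162	192	294
IGHV1-S2*01	IMGT	0	78	102	147	171	294
IGHV3-S1*01	KABAT	0	90	105	165	195	294
IGHV3-S1*01	IMGT	0	75	99	150	174	294
IGHV3-S2*01	KABAT	0	87	102	168	198	294
IGHV3-S2*01	IMGT	0	72	96	153	177	294
IGHV3-S3*01	KABAT	0	90	105	168	198	294
IGHV3-S3*01	IMGT	0	75	99	153	177	294
IGHV4-S1*01	KABAT	0	87	102	168	198	294
IGHV4-S1*01	IMGT	0	72	96	153	177	294
IGHV4-S2*01	KABAT	0	93	108	162	192	294
IGHV4-S2*01	IMGT	0	78	102	147	171	294
IGHV5-S1*01	KABAT	0	93	108	168	198	294
IGHV5-S1*01	IMGT	0	78	102	153	177	294
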