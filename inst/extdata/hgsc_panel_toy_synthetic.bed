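chr1	40807844	40907844	SIK2
chr1	45566218	45666218	CCNE1
chr1	45848316	45948316	NF1
chr1	71887942	71987942	RB1
chr1	78135684	78235684	AKT1
chr1	93215682	93315682	KRAS
chr1	104275932	104375932	CCND2
chr2	1337694	1437694	BRCA2
chr2	18603138	18703138	PIK3CA
chr2	38572797	38672797	BRCA1
chr2	48159803	48259803	TP53
chr2	82654594	82754594	TERT
chr2	93377052	93477052	MYC
chr3	10031852	10131852	AKT2
chr3	16950187	17050187	MECOM
chr3	21350931	21450931	AKT3
chr3	39433950	39533950	PTEN
chr3	53410492	53510492	PAX8
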