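mirna_id	pathway1	pathway2	genes_pathway1	genes_pathway2	predicted_direction
Hsa-miR-135b	Ethanol degradation	Mismatch repair	ACSL1/3,ALDH1A1/1B1/3A2/4A1	FEN1,MSH6,RFC2,RFC4,RPA1,SLC19A1	up
Hsa-miR-365-2	Role of BRCA1 in DNA Damage Response	Putrescine Degradation III	ATR,CHEK2,E2F1,MLH1,FANCA/B/C/E,MSH6,NBN,PLK1,RB1,RBBP8,RBL1,RFC5	ALDH1A1/1A3/2,IL4I1,MAOA,SMOX	down
Hsa-miR-365-2	Tryptophan Degradation X	Role of BRCA1 in DNA Damage response	ALDH1A1/1A3/2,IL4I1,MAOA,SMOX	ATR,CHEK2,E2F1,FANCA,FANCB,FANCC,FANCE,MLH1,MSH6,NBN,PLK1,RB1,RBBP8,RBL1,RFC5	down
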