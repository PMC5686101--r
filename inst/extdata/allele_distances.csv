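gene,distance,unit,source_key
Adh1 (maize Adh1-1F vs Adh1-1S),2.02,percent_difference,59
Pi-ta (rice blast resistance),1,amino_acid,60
Pikh (rice varieties),13,snp,62
Adh1 (wild barley),7,base_pairs,63
Adh1 (wild barley),7,base_pairs,63
Adh1 (wild barley),19,base_pairs,63
Adh1 (wild barley),45,base_pairs,63
Adh1 (wild barley),48,base_pairs,63
Adh1 (wild barley),54,base_pairs,63
Adh1 (wild barley),19,base_pairs,63
Adh1 (wild barley),56,base_pairs,63
Adh1 (wild barley),47,base_pairs,63
Adh1 (wild barley),19,base_pairs,63
HMGCR,0,synonymous_snp,35
HMGCR,1,nonsynonymous_snp,35
HMGCR,1,noncoding_snp,35
HSD3B1,3,synonymous_snp,35
HSD3B1,2,nonsynonymous_snp,35
HSD3B1,1,noncoding_snp,35
HTR1E,1,synonymous_snp,35
HTR1E,0,nonsynonymous_snp,35
HTR1E,0,noncoding_snp,35
HTR2A,2,synonymous_snp,35
HTR2A,3,nonsynonymous_snp,35
HTR2A,9,noncoding_snp,35
HTR2C,0,synonymous_snp,35
HTR2C,1,nonsynonymous_snp,35
HTR2C,0,noncoding_snp,35
HTR5A,2,synonymous_snp,35
HTR5A,0,nonsynonymous_snp,35
HTR5A,0,noncoding_snp,35
HTR6,1,synonymous_snp,35
HTR6,0,nonsynonymous_snp,35
HTR6,0,noncoding_snp,35
HTR7,0,synonymous_snp,35
HTR7,0,nonsynonymous_snp,35
HTR7,0,noncoding_snp,35
IGF1,0,synonymous_snp,35
IGF1,0,nonsynonymous_snp,35
IGF1,8,noncoding_snp,35
IGF2,0,synonymous_snp,35
IGF2,0,nonsynonymous_snp,35
IGF2,1,noncoding_snp,35
ITGA2B,4,synonymous_snp,35
ITGA2B,3,nonsynonymous_snp,35
ITGA2B,0,noncoding_snp,35
ITGB3,4,synonymous_snp,35
ITGB3,3,nonsynonymous_snp,35
ITGB3,0,noncoding_snp,35
KLK2,0,synonymous_snp,35
KLK2,1,nonsynonymous_snp,35
KLK2,2,noncoding_snp,35
LCAT,3,synonymous_snp,35
LCAT,0,nonsynonymous_snp,35
LCAT,0,noncoding_snp,35
LDLR,7,synonymous_snp,35
LDLR,3,nonsynonymous_snp,35
LDLR,0,noncoding_snp,35
LIPC,4,synonymous_snp,35
LIPC,3,nonsynonymous_snp,35
LIPC,4,noncoding_snp,35
LPL,1,synonymous_snp,35
LPL,1,nonsynonymous_snp,35
LPL,0,noncoding_snp,35
MAOA,1,synonymous_snp,35
MAOA,0,nonsynonymous_snp,35
MAOA,0,noncoding_snp,35
MAOB,1,synonymous_snp,35
MAOB,0,nonsynonymous_snp,35
MAOB,0,noncoding_snp,35
MPL,1,synonymous_snp,35
MPL,2,nonsynonymous_snp,35
MPL,1,noncoding_snp,35
NGFB,1,synonymous_snp,35
NGFB,1,nonsynonymous_snp,35
NGFB,5,noncoding_snp,35
NT3,1,synonymous_snp,35
NT3,0,nonsynonymous_snp,35
NT3,0,noncoding_snp,35
NTRK1,5,synonymous_snp,35
NTRK1,2,nonsynonymous_snp,35
NTRK1,0,noncoding_snp,35
PACE,2,synonymous_snp,35
PACE,0,nonsynonymous_snp,35
PACE,4,noncoding_snp,35
PAI1,1,synonymous_snp,35
PAI1,2,nonsynonymous_snp,35
PAI1,1,noncoding_snp,35
PAI2,5,synonymous_snp,35
PAI2,4,nonsynonymous_snp,35
PAI2,5,noncoding_snp,35
PC1,1,synonymous_snp,35
PC1,3,nonsynonymous_snp,35
PC1,1,noncoding_snp,35
PCI,5,synonymous_snp,35
PCI,5,nonsynonymous_snp,35
PCI,4,noncoding_snp,35
POMC,0,synonymous_snp,35
POMC,0,nonsynonymous_snp,35
POMC,0,noncoding_snp,35
PRL,1,synonymous_snp,35
PRL,1,nonsynonymous_snp,35
PRL,1,noncoding_snp,35
PROC,3,synonymous_snp,35
PROC,0,nonsynonymous_snp,35
PROC,0,noncoding_snp,35
PROS1,1,synonymous_snp,35
PROS1,0,nonsynonymous_snp,35
PROS1,0,noncoding_snp,35
PTAFR,0,synonymous_snp,35
PTAFR,2,nonsynonymous_snp,35
PTAFR,0,noncoding_snp,35
PTH,1,synonymous_snp,35
PTH,0,nonsynonymous_snp,35
PTH,2,noncoding_snp,35
PTHLH,0,synonymous_snp,35
PTHLH,0,nonsynonymous_snp,35
PTHLH,13,noncoding_snp,35
SELP,5,synonymous_snp,35
SELP,8,nonsynonymous_snp,35
SELP,0,noncoding_snp,35
SHBG,1,synonymous_snp,35
SHBG,3,nonsynonymous_snp,35
SHBG,1,noncoding_snp,35
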