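region,start,end,key_position
beta1-alpha1,8,16,NA
beta3-alpha3,49,58,NA
beta4-alpha4,70,78,NA
beta5-alphaA,95,106,NA
alphaBp-betaAp,118,130,NA
betaA-alphaC,146,154,NA
betaB-alphaD,175,186,180
betaG-alpha5,275,285,NA
alpha5,295,308,NA
PDXB-dim,320,380,NA
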