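region,status,forest_kha,dist_pre_ha,dist_post_ha,dist_full_ha,prop_pre_pct,prop_post_pct,prop_full_pct
EUROPE,DOCUMENTED,2401,61836,14388,NA,2.6,0.6,NA
EU,DOCUMENTED,1999,42347,10585,NA,2.1,0.5,NA
EUROPE,POTENTIAL,2943,NA,NA,61003,NA,NA,2.1
EU,POTENTIAL,2857,NA,NA,57675,NA,NA,2.0
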