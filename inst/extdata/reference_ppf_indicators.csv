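bioregion,area_kha,dist_kha,prop_pct,rate,severity
Alpine,463,10.9,2.4,0.07,0.52
Alpine-Scandinavian,1320,19.2,1.5,0.04,0.65
Atlantic,26,0.5,2.1,0.06,0.68
Black Sea,11,0.4,3.2,0.09,0.43
Boreal,905,26.0,2.9,0.08,0.70
Continental,214,3.9,1.8,0.05,0.51
Mediterranean,NA,NA,6.2,0.18,0.65
Pannonian,2,NA,0.7,0.02,0.49
Steppic,3,0.1,3.2,0.09,0.59
EUROPE,2943,61.0,2.1,0.06,0.64
EU,2857,57.7,2.0,0.06,0.63
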