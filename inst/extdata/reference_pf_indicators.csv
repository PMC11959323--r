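bioregion,area_kha,prop_total_forest_pct,dist_pre_kha,rate_pre,dist_post_kha,rate_post,rate_change,sev_pre,sev_post,sev_change
Alpine,216,0.9,4.9,0.08,2.9,0.32,0.24,0.63,0.64,0.01
Alpine-Scandinavian,506,5.4,4.0,0.03,0.8,0.04,0.02,0.66,0.77,0.10
Atlantic,14,0.1,0.3,0.07,0.1,0.14,0.08,0.75,0.69,-0.06
Black Sea,7,1.5,NA,0.02,NA,0.08,0.06,0.43,0.57,0.13
Boreal,1480,2.1,38.0,0.08,7.5,0.12,0.04,0.69,0.68,-0.01
Continental,167,0.2,14.4,0.27,3.1,0.58,0.31,0.66,0.65,-0.01
Mediterranean,10,NA,0.3,0.09,0.1,0.24,0.15,0.60,0.64,0.04
Pannonian,1,NA,NA,0.08,NA,0.39,0.32,0.50,0.63,0.14
EUROPE,2401,1.1,61.8,0.08,14.4,0.15,0.07,0.67,0.68,0.0046
EU,1999,1.1,42.3,0.07,10.6,0.10,0.04,0.68,0.68,-0.0002
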