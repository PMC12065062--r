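depth_top_cm,depth_bottom_cm,som_pct,total_c_pct,ph,cec_cmolc_kg,bd_g_cm3
0,10,3.31,1.64,6.11,13.3,1.0
10,20,3.09,1.57,6.13,14.1,1.2
20,30,2.89,1.35,6.34,14.7,1.1
30,60,2.56,1.04,6.63,15.6,1.1
60,90,1.87,0.6,6.98,14.5,1.2
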