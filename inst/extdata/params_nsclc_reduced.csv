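"name","distribution","p1","p2","lower","upper","units"
"k_growth","lognormal",-4.8283137373023,0.35,0.002,0.03,"1/day"
"d0","uniform",2,5,2,5,"cm"
"Kd_neo","loguniform",1e-12,1e-09,1e-12,1e-09,"mol/mL"
"TCC","lognormal",4.53259949315326,1,1,10000,"clones"
"k_cvg","loguniform",0.03,0.6,0.03,0.6,"1/day"
"k_exh","lognormal",-0.693147180559945,0.5,0.1,3,"1/day"
"k_cl","lognormal",-1.89711998488588,0.2,0.05,0.5,"1/day"
"BW","normal",70,10,40,120,"kg"
"k_m1_rec","lognormal",-3.91202300542815,0.7,0.002,0.2,"1/day"
"k_m2_rec","lognormal",-3.50655789731998,0.7,0.003,0.3,"1/day"
"k_prR","lognormal",-2.99573227355399,0.6,0.01,2,"1/day"
"k_pr4","lognormal",2.07944154167984,0.5,0.5,80,"1/day"
"K_M","fixed",0.01,NA,NA,NA,"-"
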