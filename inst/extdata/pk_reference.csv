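strain,variant,auc_inf_ug_day_ml,auc_sd,clearance_ml_day,clearance_sd,t_half_beta_h,t_half_sd,vss_ml_kg,vss_sd,cmax_ug_ml,cmax_sd
Tg276,wt,30.0,1.6,0.66,0.17,49.6,13.4,1.50,0.15,NA,NA
Tg276,DHS,157.9,3.4,0.11,0.01,290.9,25.6,0.59,0.11,NA,NA
Tg276,YTE,96.9,3.3,0.24,0.03,148.4,36.8,0.72,0.14,NA,NA
Tg276,LS,84.4,2.0,0.21,0.03,92.9,6.1,0.60,0.06,NA,NA
Scarlett,wt,74.8,7.35,0.27,0.03,92.1,12.3,0.65,0.04,29.9,9.2
Scarlett,DHS,356.8,16.7,0.056,0.003,381.0,85.0,0.25,0.01,45.6,18.4
Scarlett,YTE,238.1,15.9,0.084,0.006,236.8,20.8,0.33,0.02,35.5,11.6
Scarlett,LS,223.0,24.1,0.090,0.009,255.0,31.8,0.36,0.02,40.2,12.6
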