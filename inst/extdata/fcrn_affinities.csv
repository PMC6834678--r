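variant,kd_ph58_nM,kd_ph58_sd_nM,kd_ph74_low_nM,kd_ph74_medium_nM,kd_ph74_high_nM,ph74_detectable,provenance
wt,550,50,NA,NA,NA,FALSE,"SPR steady-state 1:1 fit, hFcRn:hb2m dimer; pH 7.4 not detectable at any density"
DHS,110,20,NA,NA,NA,FALSE,"SPR steady-state 1:1 fit, hFcRn:hb2m dimer; pH 7.4 not detectable at any density"
YTE,23,1,NA,4730,4290,TRUE,"SPR steady-state 1:1 fit, hFcRn:hb2m dimer; pH 7.4 binding at medium/high density"
LS,55,3,NA,946,567,TRUE,"SPR steady-state 1:1 fit, hFcRn:hb2m dimer; pH 7.4 binding at medium/high density"
EDHY,28,NA,NA,NA,NA,TRUE,"screening isolate (V264E/L309D/Q311H/N434Y); residual pH 7.4 binding, Kd not quantified"
EDHS,93,NA,NA,NA,NA,FALSE,"screening isolate (V264E/L309D/Q311H/N434S); no apparent pH 7.4 binding"
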