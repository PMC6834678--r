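strain,variant,mean_h,sd_h,n,provenance
Tg276,wt,49.6,13.4,11,"beta-phase T1/2, trastuzumab-Fc variant, hemizygous Tg276 hFcRn-transgenic mice, 2 mg/kg i.v."
Tg276,DHS,290.9,25.6,11,"beta-phase T1/2, trastuzumab-Fc variant, hemizygous Tg276 hFcRn-transgenic mice, 2 mg/kg i.v."
Tg276,YTE,148.4,36.8,11,"beta-phase T1/2, trastuzumab-Fc variant, hemizygous Tg276 hFcRn-transgenic mice, 2 mg/kg i.v."
Tg276,LS,92.9,6.1,11,"beta-phase T1/2, trastuzumab-Fc variant, hemizygous Tg276 hFcRn-transgenic mice, 2 mg/kg i.v."
Scarlett,wt,92.1,12.3,6,"beta-phase T1/2, trastuzumab-Fc variant, Scarlett knock-in mice, 2 mg/kg i.v."
Scarlett,DHS,381.0,85.0,6,"beta-phase T1/2, trastuzumab-Fc variant, Scarlett knock-in mice, 2 mg/kg i.v."
Scarlett,YTE,236.8,20.8,6,"beta-phase T1/2, trastuzumab-Fc variant, Scarlett knock-in mice, 2 mg/kg i.v."
Scarlett,LS,255.0,31.8,6,"beta-phase T1/2, trastuzumab-Fc variant, Scarlett knock-in mice, 2 mg/kg i.v."
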