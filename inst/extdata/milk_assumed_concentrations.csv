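analyte,conc,assumed_from
Bisphenol A (BPA),0.40,loq
Bisphenol F (BPF),0.028,loq
Bisphenol S (BPS),0.051,max_quantified
Mono-n-butyl phthalate (MBP),6.4,max_quantified
Perfluorooctanoic acid (PFOA),0.092,loq
Perfluorooctanesulfonic acid (PFOS),0.048,max_quantified
Prochloraz,0.082,max_quantified
8-prenylnaringenin,0.23,max_quantified
Daidzein,0.14,max_quantified
Enterodiol,0.025,max_quantified
Enterolactone,0.17,loq
Glycitein,0.011,max_quantified
Isoxanthohumol,0.078,max_quantified
Resveratrol,0.30,loq
Xanthohumol,0.22,loq
Alternariol,0.51,max_quantified
Benzophenone 1,0.039,max_quantified
Benzophenone 2,0.020,max_quantified
Butylparaben (BP),0.036,max_quantified
Ethylparaben (EP),0.13,max_quantified
Methylparaben (MP),23,max_quantified
Propylparaben (PP),16,max_quantified
Anisodamine,0.031,max_quantified
Jacobine-N-oxide,0.11,max_quantified
Riddelliin-N-oxide,0.021,loq
Scopolamine,0.0004,max_quantified
PhIP,0.042,loq
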