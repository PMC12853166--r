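metabolite,signal_ppm,multiplicity,protons,optimal_fwhm_Hz
TSP,0.00,s,9,0.78
formate,8.44,s,1,0.70
acetate,1.92,s,3,0.82
alanine,1.48,d,3,0.85
citrate,2.54,d,2,0.95
creatine,3.04,s,3,0.88
creatinine,4.06,s,2,0.86
glucose,5.23,d,1,0.92
glycine,3.56,s,2,0.84
isoleucine,1.01,d,3,0.90
lactate,1.33,d,3,0.87
leucine,0.96,t,6,0.89
lysine,1.72,m,2,0.93
phenylalanine,7.37,m,2,0.91
pyruvate,2.37,s,3,0.86
threonine,4.25,m,1,0.94
tyrosine,6.90,d,2,0.88
valine,1.10,d,6,0.90
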