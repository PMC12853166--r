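metabolite,test_value,reference_value,algorithm_factor,ratio_printed,quotient_printed
acetate,0.037,0.047,1.154,1.257,1.089
alanine,0.246,0.298,1.133,1.210,1.068
citrate,0.094,0.111,1.074,1.179,1.097
creatine,0.027,0.028,1.066,1.042,0.977
creatinine,0.074,0.090,1.252,1.225,0.978
glucose,5.647,6.525,1.120,1.156,1.032
glycine,0.182,0.204,1.115,1.124,1.008
isoleucine,0.079,0.091,1.166,1.151,0.987
lactate,1.317,1.455,1.155,1.105,0.957
leucine,0.123,0.150,1.163,1.219,1.048
lysine,0.081,0.110,1.395,1.355,0.971
phenylalanine,0.050,0.069,1.417,1.370,0.967
pyruvate,0.060,0.081,1.218,1.351,1.109
threonine,0.112,0.128,1.086,1.145,1.055
tyrosine,0.054,0.071,1.310,1.312,1.001
valine,0.216,0.256,1.106,1.184,1.070
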