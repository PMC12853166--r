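metabolite,test_value,reference_value,algorithm_factor,ratio_printed,quotient_printed
alanine,0.266,0.300,1.030,1.129,1.096
creatinine,0.047,0.060,1.350,1.282,0.950
glucose,4.520,4.560,1.000,1.009,1.009
glycine,0.244,0.245,1.050,1.005,0.957
isoleucine,0.052,0.056,1.035,1.078,1.041
leucine,0.084,0.100,1.080,1.190,1.101
threonine,0.117,0.120,1.000,1.022,1.022
valine,0.170,0.182,1.030,1.069,1.038
tyrosine,0.044,0.057,1.240,1.291,1.041
lysine,0.072,0.140,1.890,1.950,1.032
phenylalanine,0.034,0.051,1.655,1.504,0.909
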