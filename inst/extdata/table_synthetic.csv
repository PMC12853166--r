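metabolite,reference_value,test_value,algorithm_factor,ratio_printed,quotient_printed
3-hydroxyisovalerate,3.566,2.975,1.182,1.199,1.014
acetoacetate,1.955,1.636,1.195,1.195,1.000
alanine,1.801,1.743,1.005,1.033,1.028
citrate,2.109,1.758,1.206,1.200,0.995
hypoxanthine,0.904,0.635,1.299,1.424,1.096
isobutyrate,3.541,1.967,1.703,1.800,1.057
lactate,2.541,1.996,1.180,1.273,1.079
pyruvate,1.234,0.944,1.207,1.307,1.083
tryptophan,0.636,0.255,2.297,2.494,1.086
TSP,5.062,1.709,3.256,2.962,0.910
3-indoxyl sulfate,0.504,0.258,2.039,1.953,0.958
hippurate,1.348,0.767,1.700,1.757,1.034
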