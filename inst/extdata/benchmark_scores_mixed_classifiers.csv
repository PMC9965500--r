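dataset,ALVOT,C4.5,NAC,NaiveBayes,NN,AISAC-MMD
BCDR,0.770,0.749,0.678,0.727,0.729,0.784
BCWO,0.941,0.951,0.975,0.960,0.953,0.969
BCSEER,0.834,1.000,0.908,0.972,0.984,1.000
BCWD,0.934,0.931,0.894,0.930,0.960,0.965
BCWP,0.563,0.727,0.699,0.667,0.707,0.767
LCDS,0.542,0.469,0.450,0.594,0.531,0.688
MMDS,0.789,0.823,0.806,0.778,0.752,0.797
BCDS,0.728,0.741,0.731,0.727,0.682,0.731
HSDS,0.748,0.703,0.733,0.748,0.660,0.765
TSDS,0.728,0.845,0.774,0.745,0.760,0.845
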