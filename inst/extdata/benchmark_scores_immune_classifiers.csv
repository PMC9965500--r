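dataset,AIRS1,CLONALG,Immunos1,AISAC-MMD
BCDR,0.732,0.577,0.561,0.784
BCWO,0.967,0.941,0.847,0.969
BCSEER,0.945,0.965,0.954,1.000
BCWD,0.938,0.889,0.905,0.965
BCWP,0.641,0.742,0.566,0.767
LCDS,0.531,0.469,0.563,0.688
MMDS,0.634,0.700,0.743,0.797
BCDS,0.675,0.671,0.734,0.731
HSDS,0.637,0.732,0.568,0.765
TSDS,0.774,0.745,0.760,0.845
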