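parameter,range,optimum,activity_nkat_ml,sd
Time,0-120 h,96 h,24,2.07
pH,6.0-10.0,8.0,106,1.38
Temperature,25-42 C,30 C,124,1.84
CuSO4,0-1000 uM,100 uM,130,2.58
Yeast extract,0.2-1.2 %,0.6 %,229,0.89
Inoculum,0.05-1.0 %,0.3 %,240,3.75
Agitation,0-250 rpm,150 rpm,245,2.94
MnSO4,0-1000 uM,300 uM,1514,1.25
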