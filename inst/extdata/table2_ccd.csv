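run,MnSO4_uM,FeSO4_uM,ethanol_pct,predicted,actual,actual_sd,residual_printed
1,1000,500,2.0,14643.72,14935,50.97,291.28
2,300,500,5.0,10641.03,10845,35.47,203.97
3,650,350,3.5,18174.66,18222,48.13,47.34
4,300,200,5.0,11812.77,11843,37.63,30.23
5,1000,200,5.0,10139.39,11174,30.17,34.61
6,1000,200,2.0,9247.46,9365,39.58,117.54
7,650,350,3.5,18174.66,18245,27.54,70.34
8,1000,500,5.0,11334.16,11509,31.78,174.84
9,650,350,3.5,18174.66,18152,25.06,-22.66
10,650,350,3.5,18174.66,18156,37.31,-18.66
11,300,500,2.0,6134.09,6421,38.69,286.91
12,300,200,2.0,3104.33,3251,39.61,146.67
13,650,97.73,3.5,6967.65,6927,25.02,-40.65
14,650,602.27,3.5,10520.04,10106,22.47,-414.04
15,650,350,3.5,18174.66,18239,30.92,64.34
16,1238.63,350,3.5,9297.63,9085,25.65,-212.63
17,650,350,0.98,12924.89,12579,25.10,-345.89
18,61.37,350,3.5,3549.06,3007,42.50,-242.06
19,650,350,3.5,18174.66,18112,35.79,-62.66
20,650,350,6.02,17464.79,18356,27.30,-108.79
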