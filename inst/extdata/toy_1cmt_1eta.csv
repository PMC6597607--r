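"ID","TIME","AMT","EVID","SS","II","DV","MDV","WT","AGE","SEX"
1,0,10,1,0,0,,1,20,4.3,0
1,0.25,0,0,0,0,0.08654,0,20,4.3,0
1,0.5,0,0,0,0,0.1564,0,20,4.3,0
1,0.75,0,0,0,0,0.19983,0,20,4.3,0
1,1,0,0,0,0,0.21835,0,20,4.3,0
1,1.5,0,0,0,0,0.22396,0,20,4.3,0
1,2,0,0,0,0,0.25757,0,20,4.3,0
1,3,0,0,0,0,0.1972,0,20,4.3,0
1,4,0,0,0,0,0.20451,0,20,4.3,0
1,8,0,0,0,0,0.08584,0,20,4.3,0
1,12,0,0,0,0,0.04933,0,20,4.3,0
2,0,10,1,0,0,,1,35,9.6,1
2,0.25,0,0,0,0,0.04497,0,35,9.6,1
2,0.5,0,0,0,0,0.0832,0,35,9.6,1
2,0.75,0,0,0,0,0.1047,0,35,9.6,1
2,1,0,0,0,0,0.12543,0,35,9.6,1
2,1.5,0,0,0,0,0.12232,0,35,9.6,1
2,2,0,0,0,0,0.09035,0,35,9.6,1
2,3,0,0,0,0,0.08072,0,35,9.6,1
2,4,0,0,0,0,0.10061,0,35,9.6,1
2,8,0,0,0,0,0.03919,0,35,9.6,1
2,12,0,0,0,0,0.01503,0,35,9.6,1
3,0,10,1,0,0,,1,60,18.6,0
3,0.25,0,0,0,0,0.0347,0,60,18.6,0
3,0.5,0,0,0,0,0.06138,0,60,18.6,0
3,0.75,0,0,0,0,0.06239,0,60,18.6,0
3,1,0,0,0,0,0.07206,0,60,18.6,0
3,1.5,0,0,0,0,0.06802,0,60,18.6,0
3,2,0,0,0,0,0.0887,0,60,18.6,0
3,3,0,0,0,0,0.07674,0,60,18.6,0
3,4,0,0,0,0,0.08002,0,60,18.6,0
3,8,0,0,0,0,0.05978,0,60,18.6,0
3,12,0,0,0,0,0.04481,0,60,18.6,0
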