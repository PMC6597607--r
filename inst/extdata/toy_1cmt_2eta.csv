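"ID","TIME","AMT","EVID","SS","II","DV","MDV","WT","AGE","SEX"
1,0,10,1,0,0,,1,20,4.3,0
1,0.25,0,0,0,0,0.06609,0,20,4.3,0
1,0.5,0,0,0,0,0.12264,0,20,4.3,0
1,0.75,0,0,0,0,0.15388,0,20,4.3,0
1,1,0,0,0,0,0.14476,0,20,4.3,0
1,1.5,0,0,0,0,0.21395,0,20,4.3,0
1,2,0,0,0,0,0.22352,0,20,4.3,0
1,3,0,0,0,0,0.20433,0,20,4.3,0
1,4,0,0,0,0,0.21313,0,20,4.3,0
1,8,0,0,0,0,0.13469,0,20,4.3,0
1,12,0,0,0,0,0.0916,0,20,4.3,0
2,0,10,1,0,0,,1,35,9.6,1
2,0.25,0,0,0,0,0.07681,0,35,9.6,1
2,0.5,0,0,0,0,0.10614,0,35,9.6,1
2,0.75,0,0,0,0,0.1479,0,35,9.6,1
2,1,0,0,0,0,0.16081,0,35,9.6,1
2,1.5,0,0,0,0,0.15663,0,35,9.6,1
2,2,0,0,0,0,0.1969,0,35,9.6,1
2,3,0,0,0,0,0.16552,0,35,9.6,1
2,4,0,0,0,0,0.13806,0,35,9.6,1
2,8,0,0,0,0,0.08043,0,35,9.6,1
2,12,0,0,0,0,0.04761,0,35,9.6,1
3,0,10,1,0,0,,1,60,18.6,0
3,0.25,0,0,0,0,0.07676,0,60,18.6,0
3,0.5,0,0,0,0,0.11758,0,60,18.6,0
3,0.75,0,0,0,0,0.1538,0,60,18.6,0
3,1,0,0,0,0,0.17717,0,60,18.6,0
3,1.5,0,0,0,0,0.20268,0,60,18.6,0
3,2,0,0,0,0,0.16019,0,60,18.6,0
3,3,0,0,0,0,0.16732,0,60,18.6,0
3,4,0,0,0,0,0.12566,0,60,18.6,0
3,8,0,0,0,0,0.05773,0,60,18.6,0
3,12,0,0,0,0,0.02443,0,60,18.6,0
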