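age_start,width,rate
20,5,0.00045
25,5,0.00046
30,5,0.00055
35,5,0.00075
40,5,0.00119
45,5,0.00192
50,5,0.00317
55,5,0.00492
60,5,0.00758
65,5,0.01198
70,5,0.01926
75,5,0.03213
80,5,0.05555
85,5,0.09613
90,-1,0.20184
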