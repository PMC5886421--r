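age_start,width,stratum,rate,deaths,person_years
20,5,first_year,0.004,,
25,5,first_year,0.003,,
30,5,first_year,0.009,,
35,5,first_year,0.015,,
40,5,first_year,0.030,,
45,5,first_year,0.037,,
50,5,first_year,0.050,,
55,5,first_year,0.086,,
60,5,first_year,0.087,,
65,5,first_year,0.123,,
70,5,first_year,0.246,,
75,5,first_year,0.217,,
80,5,first_year,0.260,,
85,5,first_year,0.429,,
90,-1,first_year,0.471,,
20,5,survivor,0.0031,,
25,5,survivor,0.0037,,
30,5,survivor,0.0065,,
35,5,survivor,0.0083,,
40,5,survivor,0.0107,,
45,5,survivor,0.0135,,
50,5,survivor,0.0156,,
55,5,survivor,0.0193,,
60,5,survivor,0.0209,,
65,5,survivor,0.0241,,
70,5,survivor,0.0438,,
75,5,survivor,0.0669,,
80,5,survivor,0.1016,,
85,5,survivor,0.1465,,
90,-1,survivor,0.1609,,
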