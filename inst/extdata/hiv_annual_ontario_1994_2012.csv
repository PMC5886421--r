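year,new_cases,deaths,ltf,in_care
1994,1259,628,97,5976
1995,1198,667,107,6400
1996,1121,508,104,6909
1997,935,312,96,7436
1998,905,207,101,8033
1999,777,208,91,8511
2000,801,233,104,8975
2001,784,191,95,9473
2002,788,204,85,9972
2003,847,199,100,10520
2004,857,200,126,11051
2005,892,196,110,11637
2006,870,202,120,12185
2007,841,209,134,12683
2008,861,219,101,13224
2009,841,240,139,13686
2010,881,218,113,14236
2011,901,193,145,14799
2012,858,206,169,15282
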