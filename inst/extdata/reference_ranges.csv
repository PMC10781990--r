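tag,name,lo,hi
1,BMI,16,30
2,FBG,3.2,6.5
3,HbA1c,6.1,7.9
4,ALT,9,50
5,SGOT,10,40
6,BP,37,55
7,TB,3.4,28
8,SCr,50,111
9,BUN,3.1,8.0
10,TC,2.8,5.6
11,TG,0.45,1.69
12,LDL_C,1.03,1.61
13,HDL_C,1.04,1.96
14,Health,16,30
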