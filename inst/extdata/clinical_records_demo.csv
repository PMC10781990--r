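BMI,FBG,HbA1c,ALT,SGOT,BP,TB,SCr,BUN,TC,TG,LDL_C,HDL_C,health_index
24.97,5.2,126,32,31,37,15.7,73.4,3.7,2.7,1,2.3,1.15,1
25.11,5.8,102,9,12,42,6.3,59,4.7,2.9,0.9,1.09,1,1
25.82,4.9,124,23,31,37,11.6,65,5.6,5.07,1.3,2.06,1.62,1
24.56,5.4,141,35,34,45,6.5,52,7,4.1,1.8,3.24,1.62,1
24.24,5.4,140,17,18,44,13.3,68,8,5.1,1.2,3.29,1.22,1
23.59,4.7,127,24,34,43,7.3,120,4.8,3.7,1.9,2.3,1.2,0
23.44,6.5,136,33,30,43,3.4,88,3.5,5.31,1.7,2.67,1.32,1
20.44,5.6,120,12,25,37,12,50,8,5.6,1.2,2.3,1.3,0
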