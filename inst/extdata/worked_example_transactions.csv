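tid,item,quantity
1,A,1
1,C,10
1,D,1
2,B,2
2,C,4
2,E,1
2,G,2
3,A,2
3,B,2
3,D,6
3,E,2
3,F,1
4,B,4
4,C,13
4,D,3
4,E,1
5,A,2
5,C,6
5,E,2
5,G,5
6,A,6
6,B,1
6,C,1
6,D,4
6,H,2
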