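tid,item,quantity
1,A01,7
1,A02,7
1,A03,10
1,A04,9
1,A05,5
1,A06,0
1,A07,10
1,A08,4
1,A09,1
1,A10,0
1,A11,6
1,A12,4
1,A13,2
1,A14,10
2,A01,6
2,A02,3
2,A03,2
2,A04,0
2,A05,0
2,A06,4
2,A07,1
2,A08,9
2,A09,6
2,A10,0
2,A11,5
2,A12,0
2,A13,0
2,A14,10
3,A01,5
3,A02,10
3,A03,9
3,A04,6
3,A05,5
3,A06,0
3,A07,6
3,A08,7
3,A09,10
3,A10,8
3,A11,9
3,A12,2
3,A13,6
3,A14,10
4,A01,7
4,A02,6
4,A03,5
4,A04,7
4,A05,3
4,A06,7
4,A07,1
4,A08,10
4,A09,3
4,A10,4
4,A11,7
4,A12,10
4,A13,6
4,A14,10
5,A01,8
5,A02,6
5,A03,5
5,A04,3
5,A05,4
5,A06,6
5,A07,8
5,A08,6
5,A09,0
5,A10,8
5,A11,8
5,A12,10
5,A13,4
5,A14,10
6,A01,9
6,A02,9
6,A03,10
6,A04,7
6,A05,3
6,A06,5
6,A07,2
6,A08,0
6,A09,6
6,A10,2
6,A11,6
6,A12,4
6,A13,3
6,A14,0
7,A01,9
7,A02,0
7,A03,6
7,A04,8
7,A05,6
7,A06,5
7,A07,0
7,A08,0
7,A09,0
7,A10,9
7,A11,7
7,A12,7
7,A13,6
7,A14,10
8,A01,6
8,A02,5
8,A03,8
8,A04,0
8,A05,10
8,A06,0
8,A07,6
8,A08,0
8,A09,0
8,A10,10
8,A11,8
8,A12,4
8,A13,6
8,A14,0
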