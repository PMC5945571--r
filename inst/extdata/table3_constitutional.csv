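id,nCs,nCt,nCconj,nR=Cp,nR=Cs,nR=Ct,nRCO,nArOH,nOH,nHDon,nHAcc,suspect
1,0,0,1,0,0,0,0,0,0,0,2,FALSE
2,3,1,0,0,0,0,1,0,0,0,1,FALSE
3,2,2,0,0,1,1,0,0,0,0,0,FALSE
4,0,1,0,0,0,0,0,1,0,1,1,FALSE
5,3,1,0,1,1,2,0,0,1,1,1,FALSE
6,4,3,0,0,0,0,0,0,1,1,1,FALSE
7,2,1,3,1,1,2,1,0,0,0,1,FALSE
8,3,2,0,0,1,1,0,0,1,1,1,FALSE
9,4,2,0,1,1,2,0,0,0,0,0,TRUE
10,3,1,0,0,1,1,0,0,0,0,1,FALSE
11,3,1,0,0,1,1,0,0,1,1,1,FALSE
12,0,0,0,0,0,0,0,1,0,1,1,FALSE
13,0,0,0,0,0,0,0,1,0,1,1,FALSE
14,0,1,1,0,0,0,0,0,0,0,1,FALSE
15,0,1,0,0,0,0,0,0,0,0,0,FALSE
16,3,2,0,1,0,1,1,0,0,0,1,FALSE
17,0,1,0,0,0,0,0,0,0,0,0,FALSE
18,4,1,0,0,0,0,0,0,0,0,0,TRUE
19,2,0,3,0,2,2,0,0,0,0,1,FALSE
20,2,0,0,0,2,2,0,0,1,1,1,FALSE
21,4,2,4,1,3,2,0,0,0,0,0,FALSE
22,4,0,0,0,4,2,0,0,0,0,0,FALSE
23,2,2,3,0,1,1,1,0,1,1,2,FALSE
24,3,3,0,0,0,0,1,0,1,1,2,FALSE
25,0,1,0,0,0,0,0,1,0,1,1,FALSE
26,4,1,0,0,0,0,0,0,1,1,1,FALSE
27,4,2,0,1,0,1,0,0,1,1,1,FALSE
28,3,3,0,0,0,0,1,0,0,0,1,TRUE
29,2,1,0,1,1,2,0,0,1,1,1,TRUE
30,3,1,0,1,1,2,0,0,0,0,0,FALSE
31,2,1,0,1,2,1,0,0,1,1,1,FALSE
32,4,3,0,0,0,0,0,0,0,1,1,TRUE
33,3,3,0,0,0,0,1,0,0,0,1,FALSE
34,2,0,4,2,2,2,0,0,0,0,0,FALSE
35,4,2,0,1,0,1,0,0,1,1,1,FALSE
36,3,1,3,1,1,2,0,0,0,0,1,FALSE
37,2,1,4,0,2,2,0,0,0,0,0,TRUE
38,2,2,0,0,1,1,0,0,0,0,0,FALSE
39,3,2,0,1,0,1,0,0,0,0,0,FALSE
40,3,1,3,0,0,2,1,0,0,0,1,FALSE
41,3,1,3,0,0,2,1,0,0,0,2,FALSE
42,3,2,0,1,0,1,0,0,0,0,0,FALSE
43,2,1,4,0,2,2,0,0,0,0,0,FALSE
44,2,1,0,0,2,2,0,0,0,0,0,FALSE
45,3,2,0,0,1,1,0,0,1,1,1,FALSE
46,3,2,0,0,1,1,0,0,1,1,1,FALSE
47,4,2,0,1,0,1,0,0,1,1,1,FALSE
48,4,1,0,0,0,2,0,0,1,1,1,FALSE
49,3,0,0,0,1,3,0,0,0,0,0,FALSE
50,0,1,0,0,0,0,0,1,0,1,1,FALSE
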