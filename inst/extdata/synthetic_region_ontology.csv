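region_id,acronym,parent_id,group,volume_mm3
1,grey,NA,root,NA
2,Isocortex,1,CTX,NA
3,HPF,1,HPF,NA
4,TH,1,TH,NA
5,VIS,2,VIS,NA
6,RSP,2,RSP,NA
7,ACA,2,CTX,3.2
8,MO,2,CTX,8.5
9,SS,2,CTX,9.1
10,AUD,2,CTX,2.4
11,PTLp,2,CTX,1.6
12,ORB,2,CTX,2.1
13,TEa,2,CTX,1.8
14,VISp,5,VIS,4.1
15,VISpm,5,VIS,0.9
16,VISam,5,VIS,0.7
17,VISa,5,VIS,0.8
18,VISrl,5,VIS,0.6
19,VISal,5,VIS,0.6
20,VISl,5,VIS,0.9
21,VISpl,5,VIS,0.5
22,VISpor,5,VIS,0.6
23,VISli,5,VIS,0.3
24,RSPagl,6,RSP,1.6
25,RSPd,6,RSP,2.2
26,RSPv,6,RSP,2.6
27,SUB,3,HPF,1.9
28,POST,3,HPF,0.5
29,PRE,3,HPF,0.6
30,PAR,3,HPF,0.3
31,ENT,3,HPF,4.5
32,CA1,3,HPF,5.2
33,DG,3,HPF,3.9
34,ATN,4,ATN,NA
35,AD,34,ATN,0.3
36,AV,34,ATN,0.5
37,AM,34,ATN,0.5
38,LD,4,TH,0.7
39,LP,4,TH,1.2
40,CL,4,TH,0.3
41,RE,4,TH,0.4
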