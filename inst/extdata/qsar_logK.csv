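compound_id,logK_IRFMN
1,0.8835
2,1.1352
3,1.1203
4,1.2404
5,1.1834
6,1.1166
7,1.1875
8,1.2404
9,1.1352
10,1.1203
11,1.178
12,1.2404
13,1.2395
14,1.2545
15,1.2677
16,0.9916
17,1.1387
18,1.3538
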