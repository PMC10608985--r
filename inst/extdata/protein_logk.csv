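compound_id,column_id,logk
1,HSA,0.805
2,HSA,0.975
3,HSA,0.907
4,HSA,1.1899
5,HSA,0.8615
6,HSA,1.017
7,HSA,1.8991
8,HSA,1.789
9,HSA,0.9823
10,HSA,1.5981
11,HSA,1.685
12,HSA,1.8304
13,HSA,1.3649
14,HSA,1.8689
15,HSA,1.5391
16,HSA,1.4198
17,HSA,1.3603
18,HSA,1.2098
1,AGP,0.2567
2,AGP,0.2531
3,AGP,0.4257
4,AGP,0.5588
5,AGP,0.4328
6,AGP,0.4964
7,AGP,0.5881
8,AGP,0.7664
9,AGP,0.2424
10,AGP,0.3754
11,AGP,0.518
12,AGP,0.7465
13,AGP,0.4665
14,AGP,0.7971
15,AGP,0.8332
16,AGP,0.1994
17,AGP,0.5548
18,AGP,0.6494
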