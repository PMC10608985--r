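compound_id,logk_HSA,logK_HSA,ppb_HSA,logk_AGP,logK_AGP,ppb_AGP,logK_IRFMN
1,0.8050,1.0986,93.5,0.2567,0.4018,72.3,0.8835
2,0.9750,1.2775,95.9,0.2531,0.3986,72.2,1.1352
3,0.9070,1.2059,95.1,0.4257,0.5523,78.9,1.1203
4,1.1899,1.5037,97.9,0.5588,0.6707,83.2,1.2404
5,0.8615,1.1581,94.4,0.4328,0.5586,79.1,1.1834
6,1.0170,1.3217,96.4,0.4964,0.6152,81.3,1.1166
7,1.8991,2.2501,100,0.5881,0.6968,84.1,1.1875
8,1.7890,2.1342,100,0.7664,0.8556,88.6,1.2404
9,0.9823,1.2852,96.0,0.2424,0.3891,71.7,1.1352
10,1.5981,1.9333,99.8,0.3754,0.5075,77.0,1.1203
11,1.6850,2.0248,100,0.5180,0.6344,82.0,1.1780
12,1.8304,2.1778,100,0.7465,0.8378,88.2,1.2404
13,1.3649,1.6879,99.0,0.4665,0.5886,80.3,1.2395
14,1.8689,2.2183,100,0.7971,0.8829,89.3,1.2545
15,1.5391,1.8712,99.7,0.8332,0.9150,90.1,1.2677
16,1.4198,1.7456,99.2,0.1994,0.3508,69.8,0.9916
17,1.3603,1.6830,98.9,0.5548,0.6672,83.1,1.1387
18,1.2098,1.5246,98.1,0.6494,0.7514,85.8,1.3538
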