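compound_id,minus_S_C18,logkw_C18,r2_C18,minus_S_IAM,logkw_IAM,r2_IAM,n_IAM,minus_S_Chol,logkw_Chol,r2_Chol,n_Chol
1,3.7611,1.7866,0.9937,4.4559,1.0288,0.9390,8,4.0307,2.2209,0.9947,7
2,4.3603,2.0774,0.9955,4.8953,1.1961,0.9931,7,3.7822,1.9241,0.9952,6
3,4.5312,2.3929,0.9973,5.2422,1.5588,0.9818,6,4.1573,2.3437,0.9917,7
4,4.4182,2.4824,0.9986,5.3942,1.7099,0.9810,6,4.1215,2.3754,0.9959,7
5,4.7921,2.4592,0.9968,5.5312,1.4283,0.9955,7,4.3726,2.4598,0.9918,6
6,4.8532,2.7672,0.9978,6.3395,1.9101,0.9929,6,4.8849,2.9670,0.9916,6
7,4.8454,2.8451,0.9973,6.8947,2.1389,0.9847,5,5.4314,3.4508,0.9878,6
8,4.9651,3.0072,0.9972,6.9157,2.3083,0.9871,8,5.6623,3.7019,0.9747,6
9,4.2984,2.1145,0.9869,5.1370,1.1652,0.9629,7,4.2398,2.4029,0.9940,7
10,4.5132,2.5914,0.9977,6.0976,1.8779,0.9920,6,4.8387,2.9842,0.9936,8
11,4.6183,2.7340,0.9964,6.5856,2.1020,0.9781,5,5.0251,3.1674,0.9925,6
12,4.8352,2.9681,0.9957,6.8364,2.3341,0.9871,6,5.0829,3.3300,0.9908,6
13,5.1803,3.2152,0.9973,6.2034,1.5351,0.9811,6,5.4505,3.4517,0.9802,NA
14,5.6376,3.7050,0.9976,7.6211,2.6121,0.9853,6,5.1337,3.4243,0.9624,5
15,5.3305,3.3757,0.9991,7.5617,2.5780,0.9826,6,6.2128,4.2283,0.9626,6
16,5.1865,2.7200,0.9905,6.0875,1.5455,0.9942,7,5.2122,2.8538,0.9748,6
17,4.6859,2.6753,0.9990,5.7908,1.6998,0.9940,6,5.0386,3.1664,0.9782,6
18,4.6919,2.6769,0.9992,5.6500,1.6606,0.9903,6,5.0400,3.0227,0.9965,6
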