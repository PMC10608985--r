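compound_id,logP,ClogP,logP_MK,MlogP,AlogP,SlogP,SlogD
1,2.64,2.0362,1.77,2.34,2.73,2.173,2.171
2,2.8,2.1792,1.97,2.73,2.93,2.511,2.508
3,3.2,2.7492,2.42,2.86,3.39,2.747,2.742
4,4.0,3.1592,2.94,3.10,3.31,3.111,3.108
5,2.8,2.1792,1.97,2.73,2.93,2.506,2.503
6,3.2,2.7492,2.42,2.86,3.39,2.774,2.77
7,3.47,2.8992,2.66,2.98,3.48,2.867,2.864
8,4.0,3.1592,2.94,3.10,3.31,3.138,3.136
9,2.8,2.1792,1.97,2.73,2.93,2.446,2.443
10,3.2,2.7492,2.42,2.86,3.39,2.759,2.756
11,3.47,2.8992,2.66,2.98,3.48,2.86,2.858
12,4.0,3.15916,2.94,3.10,3.31,3.157,3.156
13,3.76,3.4622,3.06,3.37,4.06,3.388,3.380
14,3.76,3.4622,3.06,3.37,4.06,3.432,3.423
15,3.76,3.3422,3.06,3.37,4.06,3.407,3.401
16,1.63,1.7792,1.59,2.35,2.62,2.268,2.263
17,3.08,2.5952,2.32,2.86,3.27,2.648,2.646
18,3.64,3.2102,2.95,3.15,3.64,3.193,3.19
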