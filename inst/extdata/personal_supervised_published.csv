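participant,n_strides,n_f,n_nf,cv_accuracy,cv_f1,cv_auc
4,251,130,121,0.964000,0.966864,0.997115
5,198,98,100,0.994872,0.994872,1.000000
6,318,164,154,0.981101,0.981814,0.998506
7,159,75,84,0.968347,0.966422,0.997598
8,403,201,202,0.997531,0.997468,1.000000
9,407,221,186,0.995092,0.995506,0.999754
10,327,177,150,0.996970,0.997260,1.000000
11,368,207,161,0.970233,0.973141,0.995534
12,235,118,117,0.987234,0.987219,0.998551
13,156,100,56,0.929234,0.944859,0.984773
14,421,222,199,0.964342,0.965771,0.995683
15,261,124,137,0.950218,0.946664,0.994324
17,419,211,208,0.988038,0.988233,0.998910
18,268,104,164,0.973725,0.965086,0.996228
19,320,189,131,0.993750,0.994805,0.999595
20,420,209,211,0.988095,0.987834,0.999320
21,362,176,186,0.953044,0.951615,0.993748
22,322,169,153,0.959712,0.960859,0.997457
23,391,185,206,1.000000,1.000000,1.000000
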