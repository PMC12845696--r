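participant,n_strides,n_f,n_nf,accuracy,f1,auc
4,251,130,121,0.756972,0.738197,0.839987
5,198,98,100,0.949495,0.951456,1.000000
6,318,164,154,0.937107,0.941520,0.991448
7,159,75,84,0.905660,0.909091,1.000000
8,403,201,202,0.967742,0.968675,1.000000
9,407,221,186,0.953317,0.958242,0.996935
10,327,177,150,0.905199,0.911681,0.971337
11,368,207,161,0.907609,0.915423,0.965553
12,235,118,117,0.936170,0.939271,0.995219
13,156,100,56,0.878205,0.905473,0.949286
14,421,222,199,0.786223,0.764398,0.875617
15,261,124,137,0.773946,0.746781,0.869790
17,419,211,208,0.957041,0.958140,0.993894
18,268,104,164,0.951493,0.941176,1.000000
19,320,189,131,0.953125,0.961832,1.000000
20,420,209,211,0.959524,0.960920,1.000000
21,362,176,186,0.906077,0.903409,0.972996
22,322,169,153,0.869565,0.873494,0.950536
23,391,185,206,0.961637,0.961039,1.000000
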