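site,patient_id,f1,f2,f3,f4
A,A-00001,0.4476,0.8127,-0.1624,-0.398
A,A-00002,-0.6263,0.1858,-0.1457,1.0009
A,A-00003,0.2387,-0.6369,1.3861,-0.4477
A,A-00004,1.6402,-0.1411,0.7591,0.4377
A,A-00005,-0.5853,-0.64,1.0521,-0.7176
A,A-00006,-0.5226,0.3614,0.9068,-1.5273
A,A-00007,-0.0043,0.5664,0.2689,-0.1799
A,A-00008,-1.3913,1.4123000000000001,-0.1775,0.7171
A,A-00009,1.645,1.2771,-0.3795,0.584
A,A-00010,0.9856,-2.7898,-1.117,-0.8047
A,A-00011,0.6953,-1.6461,1.0623,2.4418
A,A-00012,-0.4485,-0.0782,-1.0765,0.9068
A,A-00013,-1.102,0.5166,-0.0711,-0.6567
A,A-00014,-0.1359,1.6404,0.1216,-1.0371
A,A-00015,0.1012,0.4074,-1.182,0.8465
A,A-00016,2.3754,-0.0764,0.7971,-0.3958
A,A-00017,-1.9077,1.7206,-0.3065,1.1805
A,A-00018,-0.9172,0.3984,1.3476,0.5613
A,A-00019,-0.8613,0.2962,-1.1763,-0.1876
A,A-00020,1.2283,1.7909,-1.4349,-0.5778
A,A-00021,-2.225,0.6907,0.3842,-0.0419
A,A-00022,-1.4015,0.9312,-0.1296,0.1723
A,A-00023,0.6503,0.3467,-1.7827,-0.6172
A,A-00024,2.3451,-0.5632,1.255,0.8191
A,A-00025,0.4645,1.0411,0.8652,-0.0815
A,A-00026,-1.2993,-0.4188,-0.9721,0.0756
A,A-00027,0.3459,0.2409,-2.1197,0.2794
A,A-00028,0.4458,1.4681,-0.4993,-0.4586
A,A-00029,-0.6767,0.2781,0.1547,0.2909
A,A-00030,-0.7814,-0.5749,2.1683,-0.1015
A,A-00031,-0.5604,-1.154,0.9116,0.4183
A,A-00032,0.3745,1.0215,1.0559,-0.9717
A,A-00033,-0.8145,0.4073,0.2342,0.4388
A,A-00034,0.3412,0.1476,0.5801,-0.1714
A,A-00035,-1.0237,-0.7275,0.3104,0.6903
A,A-00036,0.5503,0.1686,-0.9496,-0.2187
A,A-00037,2.1037,-0.1863,1.1086,1.3159
A,A-00038,0.2023,-0.6218,0.2444,-1.4751
A,A-00039,0.1898,-0.6037,-0.7543,0.4495
A,A-00040,0.5116,0.8059,0.7246,-0.2763
A,A-00041,-0.1718,-0.4276,-0.0743,1.5784
A,A-00042,-0.2016,-0.5207,1.2853,-0.9541
A,A-00043,1.006,-1.5173,-0.7541,-0.4669
A,A-00044,0.065,-1.2204,-0.124,0.1249
A,A-00045,0.2251,-1.0024,0.3558,-2.4263
A,A-00046,-0.2843,-0.3263,0.4187,-1.3631
A,A-00047,-0.1875,0.0835,2.2448,-0.5407
A,A-00048,0.6006,-1.0934,0.9307,1.1569
A,A-00049,-0.9033,0.007,0.2742,-0.64
A,A-00050,1.0308,0.5527,0.9338,0.735
A,A-00051,0.8322,2.3959,-0.757,0.0362
A,A-00052,-0.0651,-0.3185,-0.5578,-0.111
A,A-00053,0.841,-1.7226,0.3853,0.0726
A,A-00054,0.4238,0.3682,-0.6163,0.5183
A,A-00055,-2.2609,-0.0414,-0.2919,0.0753
A,A-00056,0.1815,-1.1252,0.3048,1.062
A,A-00057,-0.3498,-0.6643,-2.5861,0.4119
A,A-00058,0.2077,0.6782,0.2042,-0.1521
A,A-00059,-0.6991,-1.5577,-0.5519,-1.4383
A,A-00060,0.9717,-0.4354,-0.5262,1.2599
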