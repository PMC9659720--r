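site,patient_id,f1,f2,f3,f4
B,B-00001,3.2305,1.2931,-0.8267,-0.0341
B,B-00002,2.7885,0.6146,0.2869,0.0115
B,B-00003,2.4536,0.5012,1.3629,1.2735
B,B-00004,2.4973,-0.4157,0.1499,-0.1627
B,B-00005,2.0116,1.7415,-0.4434,0.7667
B,B-00006,2.6653,-1.4654,-0.1035,-0.6524
B,B-00007,3.3457,0.7381,0.9997,2.3231
B,B-00008,3.7504,0.5268,0.1947,-1.0277
B,B-00009,2.9766,-0.3926,0.6384,1.2149
B,B-00010,3.5931,-0.9549,0.0859,-1.7607
B,B-00011,3.273,0.1108,0.3126,-0.032
B,B-00012,2.772,0.2356,0.0498,-0.3035
B,B-00013,2.1735,-0.2722,-0.6558,0.8548
B,B-00014,1.5268,1.3656,0.8508,-1.2549
B,B-00015,3.1764,0.6611,0.4991,0.5832
B,B-00016,1.8716,-0.5189,-0.4223,-2.0757
B,B-00017,0.4997,-0.4504,-0.4906,0.3438
B,B-00018,-0.265,0.264,-0.1209,-0.2648
B,B-00019,1.4668,1.3198,-0.8114,-0.1739
B,B-00020,1.0087,-0.0336,-0.7945,-0.8661
B,B-00021,2.8833,-0.3473,0.3114,-1.4161
B,B-00022,3.4959,-1.2742,0.3473,-0.1777
B,B-00023,3.4838,0.7343,0.3854,0.8927
B,B-00024,3.4161,-0.0395,1.1158,-0.4977
B,B-00025,3.8911,0.222,-0.4458,-0.5071
B,B-00026,2.0442,-0.5594,-2.8527,-0.942
B,B-00027,4.0487,-0.0735,-0.4914,2.2466
B,B-00028,3.0234,-1.0382,0.4879,0.0882
B,B-00029,2.337,0.6931,1.3117,-0.1915
B,B-00030,2.427,-0.7033,0.3206,-0.8334
B,B-00031,5.6661,1.2547,-0.2781,-0.7546
B,B-00032,3.9596,1.5795,0.752,-1.3631
B,B-00033,2.8334,-0.0532,-0.6013,-0.4042
B,B-00034,2.7273,-0.3319,0.13,0.1012
B,B-00035,0.9724,0.1488,-0.559,-1.114
B,B-00036,2.9176,2.0859,0.2483,-0.5241
B,B-00037,2.1002,-0.8404,1.0304,-0.6791
B,B-00038,1.7894,-0.2014,0.0935,0.9217
B,B-00039,3.1476,0.4432,-0.9943,0.3391
B,B-00040,2.2173,-0.2657,0.3964,0.1643
B,B-00041,2.5706,-1.5537,1.0251,0.6531
B,B-00042,3.3565,-1.4129,-1.1848,-0.8163
B,B-00043,2.3332,-0.5581,-0.3653,1.5807
B,B-00044,3.0417,0.2341,-0.9156,0.6431
B,B-00045,2.9625,1.0046,0.3451,-2.552
B,B-00046,4.6329,0.0204,1.6618,1.3353
B,B-00047,4.2364,0.969,-1.9745,0.2537
B,B-00048,0.4625,0.8751,-0.6534,-0.6769
B,B-00049,1.5642,-2.0433,-0.877,-0.8413
B,B-00050,2.2768,-1.7555,-1.95,-1.2929
B,B-00051,2.208,-0.9381,1.992,1.8412
B,B-00052,1.8103,0.1777,0.0747,0.1408
B,B-00053,2.8691,-0.1059,-1.2429,-0.4001
B,B-00054,6.1024,-1.8843,0.0988,0.592
B,B-00055,3.6161,-0.2493,1.2426,0.0521
B,B-00056,3.3771,-0.0407,0.2569,0.0824
B,B-00057,1.7856,0.3531,1.1647,0.3128
B,B-00058,3.7512,-0.0498,-0.2242,-0.0541
B,B-00059,3.1191,-0.3101,0.8978,0.077
B,B-00060,5.2669,-0.1,0.1987,0.3933
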