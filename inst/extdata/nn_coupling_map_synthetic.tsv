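phi	psi	J
-180	-180	-2.4199
-150	-180	-3.0626
-120	-180	-3.2005
-90	-180	-2.8331
-60	-180	-2.2477
-30	-180	-1.7313
0	-180	-1.3469
30	-180	-0.9824
60	-180	-0.7642
90	-180	-0.716
120	-180	-0.9641
150	-180	-1.5915
-180	-150	-1.4139
-150	-150	-1.97
-120	-150	-2.0351
-90	-150	-1.6374
-60	-150	-1.1194
-30	-150	-0.7746
0	-150	-0.5785
30	-150	-0.3297
60	-150	-0.0944
90	-150	0.0273
120	-150	-0.1434
150	-150	-0.6788
-180	-120	-0.6048
-150	-120	-0.8309
-120	-120	-0.4258
-90	-120	0.427
-60	-120	1.1151
-30	-120	1.2125
0	-120	0.9128
30	-120	0.6909
60	-120	0.6548
90	-120	0.6485
120	-120	0.4289
150	-120	-0.0467
-180	-90	-0.1647
-150	-90	0.1361
-120	-90	1.3464
-90	-90	3.0215
-60	-90	4.0953
-30	-90	3.8983
0	-90	2.8545
30	-90	1.8661
60	-90	1.3055
90	-90	0.9914
120	-90	0.6107
150	-90	0.1579
-180	-60	-0.0953
-150	-60	0.7207
-120	-60	2.6872
-90	-60	5.1205
-60	-60	6.5644
-30	-60	6.1369
0	-60	4.4435
30	-60	2.7441
60	-60	1.6459
90	-60	0.9859
120	-60	0.4221
150	-60	-0.0132
-180	-30	-0.4613
-150	-30	0.5867
-120	-30	2.8211
-90	-30	5.4865
-60	-30	7.0644
-30	-30	6.6369
0	-30	4.8095
30	-30	2.8781
60	-30	1.5119
90	-30	0.6199
120	-30	-0.0779
150	-30	-0.5132
-180	0	-1.1647
-150	0	-0.2299
-120	0	1.7124
-90	0	4.0215
-60	0	5.4614
-30	0	5.2643
0	0	3.8545
30	0	2.2321
60	0	0.9395
90	0	-0.0086
120	0	-0.7553
150	0	-1.2081
-180	30	-1.9709
-150	30	-1.3309
-120	30	0.0742
-90	30	1.793
-60	30	2.9811
-30	30	3.0785
0	30	2.2788
30	30	1.1909
60	30	0.1548
90	30	-0.7176
120	30	-1.4371
150	30	-1.9128
-180	60	-2.78
-150	60	-2.47
-120	60	-1.5351
-90	60	-0.2714
-60	60	0.7466
-30	60	1.0915
0	60	0.7875
30	60	0.1703
60	60	-0.5944
90	60	-1.3387
120	60	-2.0094
150	60	-2.5448
-180	90	-3.4199
-150	90	-3.4286
-120	90	-2.8345
-90	90	-1.8331
-60	90	-0.8816
-30	90	-0.3652
0	90	-0.3469
30	90	-0.6164
60	90	-1.1303
90	90	-1.716
120	90	-2.3301
150	90	-2.9576
-180	120	-3.6427
-150	120	-3.949
-120	120	-3.6451
-90	120	-2.8484
-60	120	-1.9599
-30	120	-1.3498
0	120	-1.1154
30	120	-1.1002
60	120	-1.3508
90	120	-1.7351
120	120	-2.2609
150	120	-2.9618
-180	150	-3.2767
-150	150	-3.8151
-120	150	-3.7791
-90	150	-3.2145
-60	150	-2.4599
-30	150	-1.8498
0	150	-1.4814
30	150	-1.2342
60	150	-1.2168
90	150	-1.3691
120	150	-1.7609
150	150	-2.4618
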