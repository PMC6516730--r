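time_s,component,value
0.000000,1,86.989544
0.010000,1,84.407288
0.020000,1,84.516297
0.030000,1,82.160657
0.040000,1,85.200585
0.050000,1,85.070493
0.060000,1,87.487611
0.070000,1,89.210450
0.080000,1,90.724353
0.090000,1,91.427999
0.100000,1,93.086924
0.110000,1,91.186424
0.120000,1,91.490953
0.130000,1,90.905577
0.140000,1,94.499680
0.150000,1,97.635454
0.160000,1,98.023961
0.170000,1,98.297217
0.180000,1,97.181600
0.190000,1,98.429820
0.200000,1,99.431917
0.210000,1,97.200404
0.220000,1,96.951916
0.230000,1,100.844431
0.240000,1,100.820987
0.250000,1,98.713651
0.260000,1,100.262591
0.270000,1,98.509636
0.280000,1,96.030608
0.290000,1,95.619037
0.300000,1,96.470445
0.310000,1,95.525774
0.320000,1,89.344291
0.330000,1,87.105841
0.340000,1,87.629272
0.350000,1,87.722955
0.360000,1,84.828461
0.370000,1,83.617338
0.380000,1,76.481063
0.390000,1,79.349451
0.400000,1,80.450932
0.410000,1,80.372351
0.420000,1,80.822920
0.430000,1,79.109608
0.440000,1,78.407885
0.450000,1,81.820305
0.460000,1,82.892058
0.470000,1,77.067161
0.480000,1,78.900112
0.490000,1,78.525460
0.500000,1,78.577599
0.510000,1,77.706050
0.520000,1,79.470148
0.530000,1,78.876594
0.540000,1,79.189697
0.550000,1,78.518399
0.560000,1,81.928799
0.570000,1,82.946927
0.580000,1,83.290439
0.590000,1,86.159564
0.600000,1,86.349887
0.610000,1,83.735499
0.620000,1,84.175910
0.630000,1,81.192492
0.640000,1,82.563827
0.650000,1,84.189775
0.660000,1,87.174311
0.670000,1,84.883191
0.680000,1,83.777287
0.690000,1,83.057591
0.700000,1,84.386703
0.710000,1,80.423863
0.720000,1,81.202046
0.730000,1,81.293389
0.740000,1,79.434944
0.750000,1,77.466328
0.760000,1,76.395116
0.770000,1,74.505916
0.780000,1,73.968084
0.790000,1,73.780592
0.800000,1,71.511692
0.810000,1,71.911527
0.820000,1,73.306758
0.830000,1,75.397650
0.840000,1,74.009367
0.850000,1,75.245506
0.860000,1,76.770508
0.870000,1,75.539024
0.880000,1,76.998625
0.890000,1,74.629083
0.900000,1,71.318880
0.910000,1,68.839411
0.920000,1,70.028659
0.930000,1,70.064004
0.940000,1,69.727283
0.950000,1,69.391534
0.960000,1,69.270939
0.970000,1,67.946255
0.980000,1,68.683076
0.990000,1,65.568134
1.000000,1,67.531337
1.010000,1,66.757315
1.020000,1,69.209702
1.030000,1,67.281783
1.040000,1,70.777428
1.050000,1,72.545462
1.060000,1,70.689743
1.070000,1,69.263650
1.080000,1,67.234202
1.090000,1,63.018473
1.100000,1,64.744489
1.110000,1,66.987969
1.120000,1,66.573427
1.130000,1,66.865463
1.140000,1,65.251682
1.150000,1,65.159266
1.160000,1,63.091539
1.170000,1,66.214064
1.180000,1,64.443423
1.190000,1,64.602473
1.200000,1,66.272494
1.210000,1,66.458689
1.220000,1,67.046617
1.230000,1,64.720502
1.240000,1,67.917048
1.250000,1,65.694994
1.260000,1,64.048843
1.270000,1,66.465149
1.280000,1,68.023475
1.290000,1,65.805043
1.300000,1,64.958331
1.310000,1,64.474036
1.320000,1,63.807799
1.330000,1,60.544251
1.340000,1,64.791677
1.350000,1,62.902742
1.360000,1,58.781048
1.370000,1,55.090179
1.380000,1,56.418600
1.390000,1,55.929714
1.400000,1,53.349083
1.410000,1,53.984489
1.420000,1,50.422433
1.430000,1,50.290083
1.440000,1,49.547278
1.450000,1,52.646916
1.460000,1,50.781364
1.470000,1,49.918926
1.480000,1,54.129048
1.490000,1,51.606269
1.500000,1,54.683867
0.000000,2,80.572338
0.010000,2,85.208015
0.020000,2,84.570150
0.030000,2,83.313904
0.040000,2,86.246496
0.050000,2,88.130089
0.060000,2,89.346318
0.070000,2,83.585489
0.080000,2,82.992144
0.090000,2,82.814672
0.100000,2,81.789168
0.110000,2,80.633237
0.120000,2,77.920238
0.130000,2,77.176691
0.140000,2,73.695910
0.150000,2,73.066069
0.160000,2,75.754193
0.170000,2,76.129832
0.180000,2,74.177073
0.190000,2,74.064026
0.200000,2,77.376258
0.210000,2,77.205328
0.220000,2,77.963692
0.230000,2,82.017457
0.240000,2,82.362545
0.250000,2,85.155987
0.260000,2,83.941560
0.270000,2,82.933154
0.280000,2,80.353132
0.290000,2,83.944371
0.300000,2,81.398457
0.310000,2,83.231446
0.320000,2,83.000214
0.330000,2,81.761468
0.340000,2,83.504984
0.350000,2,86.992892
0.360000,2,84.156608
0.370000,2,84.189240
0.380000,2,82.624318
0.390000,2,82.502311
0.400000,2,85.058814
0.410000,2,82.102397
0.420000,2,82.097782
0.430000,2,81.619125
0.440000,2,79.090977
0.450000,2,77.800310
0.460000,2,77.195330
0.470000,2,77.583178
0.480000,2,78.728533
0.490000,2,76.652966
0.500000,2,78.159048
0.510000,2,75.034358
0.520000,2,74.947976
0.530000,2,76.706694
0.540000,2,73.787464
0.550000,2,72.978197
0.560000,2,73.068951
0.570000,2,73.315699
0.580000,2,70.587383
0.590000,2,66.385843
0.600000,2,64.981327
0.610000,2,64.995808
0.620000,2,67.909416
0.630000,2,70.086853
0.640000,2,69.964242
0.650000,2,71.744732
0.660000,2,68.715081
0.670000,2,68.257230
0.680000,2,69.141447
0.690000,2,68.195567
0.700000,2,69.152852
0.710000,2,71.237524
0.720000,2,68.466044
0.730000,2,65.636369
0.740000,2,66.442803
0.750000,2,64.771709
0.760000,2,67.041567
0.770000,2,61.187319
0.780000,2,64.631806
0.790000,2,64.553404
0.800000,2,67.277881
0.810000,2,68.931250
0.820000,2,69.378395
0.830000,2,67.213377
0.840000,2,67.041474
0.850000,2,65.769275
0.860000,2,62.561286
0.870000,2,62.606056
0.880000,2,62.308714
0.890000,2,60.638173
0.900000,2,59.766823
0.910000,2,56.254684
0.920000,2,54.597761
0.930000,2,56.556051
0.940000,2,59.217040
0.950000,2,57.282056
0.960000,2,56.134833
0.970000,2,57.783376
0.980000,2,56.941885
0.990000,2,56.271327
1.000000,2,55.216232
1.010000,2,55.807015
1.020000,2,58.984242
1.030000,2,56.873613
1.040000,2,58.042720
1.050000,2,61.014162
1.060000,2,59.912790
1.070000,2,58.586975
1.080000,2,59.499792
1.090000,2,57.046718
1.100000,2,57.380818
1.110000,2,55.973220
1.120000,2,59.677938
1.130000,2,57.966876
1.140000,2,59.537185
1.150000,2,58.186892
1.160000,2,57.422509
1.170000,2,55.916842
1.180000,2,53.934513
1.190000,2,51.510596
1.200000,2,50.567018
1.210000,2,52.299306
1.220000,2,50.890313
1.230000,2,47.618591
1.240000,2,47.117838
1.250000,2,46.063408
1.260000,2,47.753351
1.270000,2,46.377446
1.280000,2,39.996951
1.290000,2,41.026908
1.300000,2,37.521981
1.310000,2,38.248628
1.320000,2,41.404118
1.330000,2,42.480820
1.340000,2,42.707669
1.350000,2,47.931372
1.360000,2,49.330269
1.370000,2,51.513720
1.380000,2,57.023843
1.390000,2,57.134067
1.400000,2,56.496662
1.410000,2,56.474503
1.420000,2,55.515258
1.430000,2,54.687544
1.440000,2,54.779612
1.450000,2,53.033676
1.460000,2,53.369076
1.470000,2,53.707314
1.480000,2,53.161995
1.490000,2,56.201289
1.500000,2,54.759442
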