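data_llgfold
_cell.length_a    24.5208
_cell.length_b    24.5961
_cell.length_c    13.7248
_cell.angle_alpha 90.0000
_cell.angle_beta  90.0000
_cell.angle_gamma 90.0000
_symmetry.space_group_name_H-M 'P 21 21 21'
loop_
_refln.index_h
_refln.index_k
_refln.index_l
_refln.intensity_meas
_refln.intensity_sigma
3 6 0 -22.2608619 33.9327831
2 6 0 1351.74038 100.185148
1 6 0 59.1748581 33.7994165
0 6 0 591.686099 66.8888683
4 5 0 103.061919 38.8330027
3 5 0 5.32650819 33.5681561
2 5 0 299.960025 46.8632347
1 5 0 10.7861211 34.4765905
5 4 0 68.6346266 33.6199241
4 4 0 2405.27829 154.862647
3 4 0 36.2050935 34.6115633
2 4 0 199.353421 41.4567433
1 4 0 -4.82199384 33.9495783
0 4 0 3424.93217 215.999071
6 3 0 103.367276  35.526621
5 3 0  143.14209 45.9962115
4 3 0 137.467712 38.6974822
3 3 0 334.665068 50.1675226
2 3 0 419.431477 51.8689421
1 3 0 293.168282 47.1631506
6 2 0 1687.03056 106.719097
5 2 0 -34.7119089 33.8174096
4 2 0 232.816279 41.8394226
3 2 0 82.7363703 34.3079043
2 2 0  1124.5066 89.7272635
1 2 0 -78.0077171 33.7624851
0 2 0 6448.33792 347.645512
6 1 0 100.739472  39.746618
5 1 0 137.312729 38.8508344
4 1 0 72.5475902 36.6211243
3 1 0 187.854853 41.3876808
2 1 0 404.119597 52.8866287
1 1 0 205.538716 41.5645095
6 0 0 631.995512 66.0624695
4 0 0 3695.88645 227.139074
2 0 0 6266.04612  357.47302
3 6 1 -27.6999807 35.1746211
2 6 1  146.40116  42.774525
1 6 1 49.1237897  37.014958
0 6 1  771.98764 73.0235288
4 5 1 612.669703 65.4121307
3 5 1 -46.4281203 34.5910519
2 5 1 174.559863 44.1083919
1 5 1 1742.47591 110.162869
0 5 1 31.7136981 34.0499756
5 4 1 175.219042 38.4568151
4 4 1  27.782715 35.4547643
3 4 1  50.725086 36.2248813
2 4 1  758.32607 72.1043313
1 4 1 18.2002877 36.6296207
0 4 1 103.103249 40.3713892
6 3 1 445.929079 50.5934719
5 3 1 -9.42091088 34.0091166
4 3 1 422.511615  51.372812
3 3 1 880.551644 81.8382433
2 3 1 -25.4872453 35.7652278
1 3 1 506.330714 59.8064087
0 3 1 436.548451 52.8772181
6 2 1 504.875322 55.6007504
5 2 1 164.670006 38.5366563
4 2 1 136.038538 44.2856898
3 2 1 419.751318 49.4857716
2 2 1 1253.16987 99.6873076
1 2 1 192.179465  42.794629
0 2 1 46.8344166 34.9803921
6 1 1  230.91908 46.9969013
5 1 1 1235.39707 105.875373
4 1 1 333.520509 51.4326764
3 1 1 508.149826 58.6845741
2 1 1 391.961553 55.6121608
1 1 1 512.270957 61.9932787
0 1 1 2240.73223 143.194766
6 0 1 213.713605 44.5251395
5 0 1 248.500279 44.9713161
4 0 1 -1.31459234 33.5484719
3 0 1 -30.3792733 33.5256976
2 0 1 210.801525 41.3679788
1 0 1 227.280263 43.2202516
0 6 2 82.2196924  35.753497
3 5 2 524.166432 64.2630777
2 5 2 39.1442007  33.798173
1 5 2 369.917037 56.8392369
0 5 2 120.426174 40.6289111
4 4 2 716.648108  74.465852
3 4 2 206.744424 49.3043045
2 4 2 145.900942 37.4107816
1 4 2 479.794228 59.4562122
0 4 2 362.139294 52.3765821
5 3 2 389.291989 54.0341092
4 3 2 19.0899316 33.8245925
3 3 2 402.028682 49.6523608
2 3 2 217.502874  40.956517
1 3 2  1313.4707 105.437442
0 3 2 -35.6527496 34.0545295
5 2 2  229.35807 48.6733253
4 2 2 44.8592048 38.1578346
3 2 2 339.340115 45.9859471
2 2 2 7.22498706  33.872386
1 2 2  150.30364 42.8443321
0 2 2 1432.40253 108.402578
5 1 2 498.459381 55.4671926
4 1 2 37.1820847  34.928081
3 1 2 635.682197 66.3508057
2 1 2  15.523102 35.6359292
1 1 2 3532.87339 219.636256
0 1 2 227.789113 40.7415271
6 0 2 65.1031997 35.1283536
5 0 2 127.372094 36.2517676
4 0 2 375.178438  53.408249
3 0 2 1666.73644 118.947451
2 0 2 1582.14488 118.730395
1 0 2 8062.57547 442.191734
0 0 2 9691.62284  506.16333
2 4 3 673.581182 62.9274164
1 4 3 81.9106162 36.5875396
0 4 3  117.86675 38.5387776
3 3 3 73.7364347 35.0534491
2 3 3 113.593289 37.0771236
1 3 3  14.438504 34.0644509
0 3 3 932.873547 83.4355875
4 2 3 534.765359 56.7410074
3 2 3 284.067638 47.3983846
2 2 3 1379.35869 94.4164336
1 2 3 284.279369 48.7885723
0 2 3 31.4018354 37.0274348
4 1 3 346.568449 49.5214232
3 1 3 -16.1969629 33.8474258
2 1 3 274.906243  45.806331
1 1 3 -55.0306973  33.675349
0 1 3 2093.19728 151.371678
4 0 3 368.596589 50.2217565
3 0 3 32.2729291 34.5657331
2 0 3 121.572923  37.949886
1 0 3  4.1205998 37.5117621
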