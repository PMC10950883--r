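BEGIN IONS
TITLE=syn|pair0001
PEPMASS=1503.705492
CHARGE=2+
72.044390 135.013452
147.112804 169.656293
173.092068 164.125019
260.196868 88.117519
302.134661 310.071659
375.223811 306.632252
430.229624 495.006840
497.727446 396.318058
498.265153 1126.252058
503.318774 194.087961
547.799360 184.423282
548.251285 859.128876
576.762017 732.467694
612.280574 157.013574
612.320656 348.835480
632.361367 419.700558
638.278031 337.857072
669.834128 137.699504
676.309863 690.574962
704.820594 226.900891
745.445431 516.724470
751.365792 85.834896
753.304974 383.769235
753.346976 217.754967
799.892174 261.679317
828.402906 443.583419
834.878641 562.809874
866.389038 211.304092
892.392112 465.257303
892.432194 216.975961
892.513845 379.441801
927.950751 176.146145
956.461483 252.458710
956.913409 440.031757
994.447616 576.965977
995.523029 629.092311
1006.447616 186.823542
1006.985322 564.683560
1057.952208 455.584323
1071.014611 98.339661
1094.591443 273.645753
1095.495294 709.952979
1127.556643 340.332528
1131.486415 1551.707303
1152.516758 88.853615
1185.070115 345.604401
1188.028447 618.803800
1223.553872 113.522402
1223.634036 154.445781
1252.549743 80.969450
1289.094318 360.107872
1316.597225 4609.437069
1338.660979 164.024914
1351.612449 299.681647
1353.141800 523.453193
1374.110696 131.632254
1408.633913 475.406543
1417.663096 491.975342
1430.652728 109.435962
1468.186935 637.123666
1501.724308 388.337585
1505.686677 615.933937
1598.777072 203.400429
1655.798535 274.055435
1668.750005 176.871299
1783.776948 128.117028
1783.857113 197.745259
1854.894227 277.712799
1911.915690 149.224616
1912.819541 249.790369
2011.887955 538.718044
2012.963369 175.963116
2114.897140 730.345614
2141.021946 240.213634
2254.106010 491.831290
2261.965554 409.821069
2369.132953 586.481572
2375.049618 194.935868
2504.092211 100.343446
2577.181360 290.120256
2632.187174 313.714886
2705.276323 718.409200
2747.214117 745.977104
2834.318916 155.934834
2860.298181 621.831861
2935.366595 598.445125
END IONS

BEGIN IONS
TITLE=syn|pair0002
PEPMASS=911.957757
CHARGE=2+
88.039304 222.918230
175.118952 225.829921
201.123368 81.042788
246.156065 279.338244
298.176132 313.890254
374.251029 98.849683
465.243597 112.595016
502.309606 152.333590
505.234907 92.797265
506.224539 145.051290
538.777804 352.134134
553.761289 340.134483
573.346720 232.341840
582.272020 471.708042
602.807093 497.989694
619.308603 252.012198
625.788035 239.414876
659.349125 113.869366
660.378748 271.184372
661.306592 251.444692
717.400212 128.812463
725.335880 756.098697
747.367180 249.170571
763.373328 454.700761
789.383362 368.200515
811.899710 870.979135
814.452976 229.220254
824.901919 468.273534
868.441742 245.043433
894.435594 161.801437
929.479919 126.961993
1009.462537 221.327242
1076.548333 484.451198
1106.515301 427.852133
1163.536765 82.250240
1204.606910 308.418040
1250.568793 269.168348
1317.690974 485.324203
1321.605907 410.960792
1449.664485 1083.577452
1525.739381 294.244618
1577.759448 95.097680
1622.792145 321.847331
1648.796562 303.580692
1735.876209 497.404053
END IONS

BEGIN IONS
TITLE=syn|pair0003
PEPMASS=470.242732
CHARGE=2+
130.049869 160.861346
147.112804 615.316073
243.133933 190.950580
355.161210 371.794808
371.228896 693.136289
470.188153 302.401456
470.297310 456.852813
569.256567 203.757182
585.324253 222.477714
697.351530 351.015832
793.372660 140.242278
810.435594 351.196492
END IONS

BEGIN IONS
TITLE=syn|pair0004
PEPMASS=720.327198
CHARGE=2+
147.112804 402.591854
209.055683 174.788022
246.181218 160.154015
324.082626 208.505621
374.239795 214.063967
421.135390 875.527545
477.168906 322.544938
487.323859 266.197034
510.263141 79.250868
533.710938 138.350397
549.193967 118.025313
558.789523 329.487851
574.355888 54.773933
597.740227 170.622339
616.302995 902.415685
647.274434 618.805204
664.220910 979.116680
705.396372 262.205443
735.258024 306.476813
776.433486 668.952079
866.298509 500.959276
891.460429 457.180053
953.330537 458.894363
1019.519006 375.141642
1066.414601 713.732889
1116.571770 705.145633
1194.473178 73.011933
1231.598713 406.937215
1293.541592 385.371227
END IONS

BEGIN IONS
TITLE=syn|pair0005
PEPMASS=1257.031392
CHARGE=2+
147.112804 254.867131
209.055683 196.106907
284.171716 52.646859
324.082626 132.088959
399.198659 84.188006
421.135390 270.039363
456.220122 181.777569
477.168906 305.159943
496.192913 284.595709
533.710938 179.705563
546.716752 236.109823
549.193967 222.586583
557.267801 170.051204
597.740227 205.573613
610.764234 308.786613
647.274434 929.678446
660.298441 337.872223
664.220910 80.714829
672.294744 42.247793
711.321916 266.615502
724.327729 2003.133442
735.258024 626.956442
761.845755 106.660892
773.342422 744.438727
780.869761 399.209099
813.350347 337.666641
824.385776 324.767560
866.298509 265.773264
870.863819 455.820321
888.369365 212.547315
889.906018 928.124101
921.387658 241.859023
925.424575 255.259474
953.330537 352.446399
978.901129 206.493064
982.938046 262.417430
991.378550 145.345856
1029.424969 1575.565855
1046.967335 286.220393
1057.935701 560.352665
1066.414601 343.211130
1092.426228 261.750197
1095.493717 377.447447
1115.449172 188.813886
1153.007188 276.441792
1183.978628 263.183583
1194.473178 551.941626
1220.521191 327.505183
1293.541592 250.415614
1319.589605 146.762440
1421.636555 265.825635
1447.648183 146.720748
1522.684234 793.431950
1560.732247 386.159304
1625.693418 262.954127
1647.764275 953.500353
1740.720361 411.302741
1778.804760 512.013160
1841.768040 906.445437
1849.841873 394.630282
1956.794983 389.770194
1964.868817 243.443882
2057.842661 56.867080
2092.927394 710.203545
2114.864125 353.088253
2189.980158 80.837208
2229.891068 522.460021
2305.007101 353.621301
2366.949980 315.499313
END IONS

BEGIN IONS
TITLE=syn|pair0006
PEPMASS=1574.322118
CHARGE=2+
102.054954 653.015953
147.112804 247.627870
231.097548 359.212339
260.196868 1250.162598
394.160876 375.968058
407.265282 152.591689
451.182340 161.459236
469.770928 111.710707
480.755475 162.077068
526.792392 95.889569
538.214368 410.944256
538.268946 154.916419
573.787503 277.186940
592.312634 721.034305
615.313688 217.980969
643.817226 151.111881
651.298432 584.200915
651.838059 735.230474
693.351433 433.744596
708.380091 139.208128
712.366452 300.169410
748.351196 39.964792
749.893465 232.894903
756.906473 552.458642
818.422921 265.054428
825.435929 293.083669
825.450516 1151.577232
861.435260 530.281124
866.949303 432.343759
881.977961 1358.268952
923.491335 1118.119651
931.512168 134.323842
938.534580 289.170441
960.503674 326.727515
983.016760 432.229467
1001.541891 246.379072
1037.060448 1043.527727
1048.537002 206.592613
1052.577508 408.202916
1075.530617 219.949470
1094.573919 334.140203
1105.558466 366.473916
1144.108126 152.363648
1146.567731 425.756520
1162.100498 264.916424
1183.617992 395.305465
1200.650158 234.928858
1218.642530 144.740974
1249.176540 155.125579
1267.168912 803.662469
1286.627177 863.273664
1302.668842 253.909378
1305.718572 153.187181
1349.234586 1124.279720
1371.193115 312.913954
1377.745318 244.756410
1385.695591 490.542514
1415.752906 394.314666
1444.727322 1236.545253
1459.276982 724.600661
1498.779655 355.259198
1501.269354 132.152836
1512.805670 260.526287
1523.798279 336.216655
1635.838566 418.496118
1649.864581 168.129899
1732.891330 292.822983
1762.948645 336.977854
1845.975394 319.260355
1862.017059 307.492412
1965.026244 401.302895
2002.076505 201.035789
2073.113619 168.710169
2096.066728 370.061611
2188.140562 1348.585499
2210.109656 317.170412
2287.208976 164.933109
2323.193720 333.505535
2400.293040 231.601404
2436.277784 204.972771
2497.345804 306.114707
2533.330548 316.968276
2610.429868 422.566302
2697.461896 367.320628
2741.378954 376.055018
2754.483360 623.700351
2888.447368 232.939543
2917.546688 1402.924860
3001.531432 257.950946
3046.589282 140.969967
END IONS

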