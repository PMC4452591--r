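T,S,TA,DIC,pH_total,omega_ara,omega_cal
15,30,2100,1800,8.30124413,3.25955461,5.13486049
15,30,2100,2000,7.83404478,1.32615957,2.08913340
15,30,2100,2200,7.16205518,0.30637152,0.48263497
15,30,2300,1800,8.56978643,5.51252672,8.68402559
15,30,2300,2000,8.26667407,3.37341138,5.31422199
15,30,2300,2200,7.81720965,1.40487479,2.21313551
15,30,2500,1800,8.77350214,7.89167165,12.43195399
15,30,2500,2000,8.52807423,5.66469030,8.92373281
15,30,2500,2200,8.23536538,3.47763366,5.47840605
15,35,2100,1800,8.23181714,3.08472606,4.80326135
15,35,2100,2000,7.77484559,1.27919601,1.99185038
15,35,2100,2200,7.13251615,0.31603087,0.49209519
15,35,2300,1800,8.49745001,5.20573617,8.10590985
15,35,2300,2000,8.19897182,3.20279885,4.98711382
15,35,2300,2200,7.75955264,1.35972128,2.11723717
15,35,2500,1800,8.69881512,7.45217807,11.60386959
15,35,2500,2000,8.45768091,5.36556638,8.35478326
15,35,2500,2200,8.16915735,3.31116163,5.15584670
15,40,2100,1800,8.17018414,2.89512984,4.49202103
15,40,2100,2000,7.72326580,1.22379345,1.89881152
15,40,2100,2200,7.10859947,0.32189922,0.49945189
15,40,2300,1800,8.43284744,4.87224124,7.55966444
15,40,2300,2000,8.13887870,3.01472205,4.67757772
15,40,2300,2200,7.70935710,1.30480405,2.02450582
15,40,2500,1800,8.63181944,6.97000745,10.81451325
15,40,2500,2000,8.39481869,5.03570905,7.81329756
15,40,2500,2200,8.11040811,3.12479213,4.84836008
20,30,2100,1800,8.22335408,3.35151559,5.21836480
20,30,2100,2000,7.76168171,1.38075757,2.14986221
20,30,2100,2200,7.10777057,0.33265638,0.51795145
20,30,2300,1800,8.48977786,5.64187564,8.78449301
20,30,2300,2000,8.18883044,3.46911816,5.40147394
20,30,2300,2200,7.74506765,1.46344908,2.27861424
20,30,2500,1800,8.69165522,8.04895441,12.53235418
20,30,2500,2000,8.44823678,5.79986232,9.03048086
20,30,2500,2200,8.15757661,3.57687383,5.56925128
20,35,2100,1800,8.15459038,3.16513933,4.87003248
20,35,2100,2000,7.70311995,1.32909171,2.04500311
20,35,2100,2200,7.07801133,0.34176222,0.52585145
20,35,2300,1800,8.41817279,5.31687516,8.18079460
20,35,2300,2000,8.12175378,3.28655321,5.05684560
20,35,2300,2200,7.68802403,1.41339259,2.17471242
20,35,2500,1800,8.61779347,7.58500117,11.67064012
20,35,2500,2000,8.37850835,5.48165626,8.43433455
20,35,2500,2200,8.09196487,3.39810135,5.22847882
20,40,2100,1800,8.09352117,2.96451545,4.54412870
20,40,2100,2000,7.65208835,1.26893243,1.94507075
20,40,2100,2200,7.05387246,0.34678650,0.53156832
20,40,2300,1800,8.35420128,4.96629843,7.61254229
20,40,2300,2000,8.06219729,3.08705204,4.73195772
20,40,2300,2200,7.63835851,1.35348357,2.07467414
20,40,2500,1800,8.55152545,7.08032399,10.85300583
20,40,2500,2000,8.31622260,5.13388927,7.86943229
20,40,2500,2200,8.03373144,3.19995925,4.90502644
25,30,2100,1800,8.14675065,3.46032216,5.31469877
25,30,2100,2000,7.69129374,1.44548728,2.22011972
25,30,2100,2200,7.05703476,0.36447572,0.55979721
25,30,2300,1800,8.41089298,5.79717708,8.90386748
25,30,2300,2000,8.11235793,3.58286431,5.50291091
25,30,2300,2200,7.67498982,1.53312582,2.35472351
25,30,2500,1800,8.61077756,8.24113639,12.65753751
25,30,2500,2000,8.36961123,5.96265072,9.15801796
25,30,2500,2200,8.08123477,3.69528684,5.67558035
25,35,2100,1800,8.07862774,3.26030918,4.94634896
25,35,2100,2000,7.63336726,1.38823994,2.10615583
25,35,2100,2200,7.02701893,0.37284298,0.56565540
25,35,2300,1800,8.33999486,5.45063152,8.26937694
25,35,2300,2000,8.04588618,3.38620081,5.13734433
25,35,2300,2200,7.61855680,1.47724327,2.24118644
25,35,2500,1800,8.53772676,7.74832735,11.75530567
25,35,2500,2000,8.30052266,5.62191698,8.52924115
25,35,2500,2200,8.01620075,3.50202162,5.31306084
25,40,2100,1800,8.01810262,3.04673323,4.60308385
25,40,2100,2000,7.58288360,1.32246506,1.99801462
25,40,2100,2200,7.00262183,0.37679003,0.56926418
25,40,2300,1800,8.27663061,5.07989400,7.67483603
25,40,2300,2000,7.98684848,3.17328526,4.79428194
25,40,2300,2200,7.56942030,1.41143225,2.13242857
25,40,2500,1800,8.47217029,7.21705196,10.90370989
25,40,2500,2000,8.23878929,5.25304562,7.93643801
25,40,2500,2200,7.95846740,3.29006122,4.97071011
30,30,2100,1800,8.07121421,3.58664237,5.42384784
30,30,2100,2000,7.62270771,1.52131800,2.30059106
30,30,2100,2200,7.00952344,0.40275715,0.60906365
30,30,2300,1800,8.33290015,5.97911223,9.04182565
30,30,2300,2000,8.03705210,3.71551509,5.61873375
30,30,2300,2200,7.60681075,1.61502444,2.44229726
30,30,2500,1800,8.53063662,8.46895539,12.80705481
30,30,2500,2000,8.29197890,6.15398197,9.30626987
30,30,2500,2200,8.00614888,3.83393010,5.79780512
30,35,2100,1800,8.00369645,3.37062099,5.03195209
30,35,2100,2000,7.56540354,1.45744604,2.17580045
30,35,2100,2200,6.97921270,0.41012231,0.61226576
30,35,2300,1800,8.26266768,5.60724488,8.37097606
30,35,2300,2000,7.97115272,3.50230800,5.22854576
30,35,2300,2200,7.55097504,1.55221450,2.31727894
30,35,2500,1800,8.45836160,7.94229689,11.85694196
30,35,2500,2000,8.22349007,5.78681018,8.63904655
30,35,2500,2200,7.94166320,3.62366615,5.40971961
30,40,2100,1800,7.94368401,3.14194158,4.66846654
30,40,2100,2000,7.51545756,1.38504959,2.05798151
30,40,2100,2200,6.95451940,0.41267764,0.61317873
30,40,2300,1800,8.19987187,5.21292097,7.74563960
30,40,2300,2000,7.91260539,3.27374427,4.86430610
30,40,2300,2200,7.50235684,1.47942990,2.19821687
30,40,2500,1800,8.39348221,7.37986721,10.96540539
30,40,2500,2000,8.16227149,5.39326966,8.01361143
30,40,2500,2200,7.88440450,3.39558249,5.04533991
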