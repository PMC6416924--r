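feature	coefficient
(Intercept)	0.4
gc_count	0
p1_A	0.00841
p2_A	0.00909
p3_A	0.00141
p4_A	-0.00757
p5_A	-0.00959
p6_A	-0.00279
p7_A	0.00657
p8_A	0.00989
p9_A	0.00412
p10_A	-0.00544
p11_A	-0.01
p12_A	-0.00537
p13_A	0.0042
p14_A	0.00991
p15_A	0.0065
p16_A	-0.00288
p17_A	-0.00961
p18_A	-0.00751
p19_A	0.0015
p20_A	0.00913
p21_A	0.00837
p22_A	-9e-05
p23_A	-0.00846
p24_A	-0.00906
p25_A	-0.00132
p26_A	0.00763
p27_A	0.00956
p28_A	0.00271
p29_A	-0.00664
p30_A	-0.00988
p1_C	0.00909
p2_C	-0.00757
p3_C	-0.00279
p4_C	0.00989
p5_C	-0.00544
p6_C	-0.00537
p7_C	0.00991
p8_C	-0.00288
p9_C	-0.00751
p10_C	0.00913
p11_C	-9e-05
p12_C	-0.00906
p13_C	0.00763
p14_C	0.00271
p15_C	-0.00988
p16_C	0.00551
p17_C	0.00529
p18_C	-0.00992
p19_C	0.00296
p20_C	0.00745
p21_C	-0.00917
p22_C	0.00018
p23_C	0.00902
p24_C	-0.00768
p25_C	-0.00262
p26_C	0.00987
p27_C	-0.00559
p28_C	-0.00522
p29_C	0.00993
p30_C	-0.00305
p1_G	0.00141
p2_G	-0.00279
p3_G	0.00412
p4_G	-0.00537
p5_G	0.0065
p6_G	-0.00751
p7_G	0.00837
p8_G	-0.00906
p9_G	0.00956
p10_G	-0.00988
p11_G	0.01
p12_G	-0.00992
p13_G	0.00964
p14_G	-0.00917
p15_G	0.00851
p16_G	-0.00768
p17_G	0.0067
p18_G	-0.00559
p19_G	0.00436
p20_G	-0.00305
p21_G	0.00167
p22_G	-0.00027
p23_G	-0.00115
p24_G	0.00254
p25_G	-0.00388
p26_G	0.00514
p27_G	-0.0063
p28_G	0.00733
p29_G	-0.00822
p30_G	0.00894
p1_T	-0.00757
p2_T	0.00989
p3_T	-0.00537
p4_T	-0.00288
p5_T	0.00913
p6_T	-0.00906
p7_T	0.00271
p8_T	0.00551
p9_T	-0.00992
p10_T	0.00745
p11_T	0.00018
p12_T	-0.00768
p13_T	0.00987
p14_T	-0.00522
p15_T	-0.00305
p16_T	0.0092
p17_T	-0.00898
p18_T	0.00254
p19_T	0.00566
p20_T	-0.00994
p21_T	0.00733
p22_T	0.00035
p23_T	-0.00779
p24_T	0.00984
p25_T	-0.00506
p26_T	-0.00322
p27_T	0.00927
p28_T	-0.0089
p29_T	0.00237
p30_T	0.00581
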