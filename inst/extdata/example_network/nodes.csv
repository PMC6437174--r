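id,x,y,z
1,107.41328345611691,-161.25421524047852,-5.515787471085787
2,-123.0325810611248,-98.19694915786386,-88.52321924641728
3,-71.14108810201287,135.7195825316012,-98.88334078714252
4,-84.29505527019501,-101.10688079148531,46.45515326410532
5,127.78259422630072,150.8180276490748,9.371454548090696
6,-23.907387163490057,60.47837883234024,129.2044618166983
7,162.84760935232043,-71.75355842337012,-54.952634032815695
8,70.04364719614387,-135.47983719035983,50.20953603088856
9,-67.63978460803628,-4.720516037195921,167.62672290205956
10,-20.87106704711914,123.63597620278597,94.6553798392415
11,4.503083601593971,189.07631700858474,13.192787766456604
12,-10.005041118711233,123.92418775707483,39.449118822813034
13,60.57649087160826,14.695248752832413,188.87173254042864
14,37.42013303562999,29.909297171980143,-73.27033216133714
15,-22.969428822398186,-95.2760242857039,-59.711612947285175
16,105.96934659406543,-5.719557777047157,143.49902076646686
17,99.58217879757285,-119.50461268424988,93.61115163192153
18,-38.25424565002322,154.81638265773654,117.3510697670281
19,63.166184071451426,-33.47099479287863,82.23311603069305
20,4.233435820788145,-122.75918703526258,-119.88367717713118
21,-184.1448205523193,-19.165676552802324,58.487387001514435
22,-187.4400245025754,24.660693295300007,52.33954703435302
23,-38.25018210336566,67.34154326841235,139.82128584757447
24,-45.300351828336716,-78.71341872960329,-89.98725898563862
25,14.00157194584608,155.28798522427678,-55.73765626177192
26,65.61126075685024,103.32946702837944,107.30545837432146
27,158.33397712558508,86.82910157367587,25.32869055867195
28,-175.41286889463663,17.441472876816988,50.977453123778105
29,-22.066466603428125,146.25054178759456,-51.48311508819461
30,1.7982034012675285,143.74135257676244,22.95300317928195
31,-141.0112828016281,83.67881923913956,88.86161958798766
32,2.900936920195818,-174.04821813106537,-84.71218692138791
33,102.90163718163967,83.26176768168807,-36.88067905604839
34,-59.40522933378816,-175.79343570396304,59.305392764508724
35,179.8884996213019,-83.98178145289421,7.63552812859416
36,-4.932877141982317,-129.62029743939638,-61.013372614979744
37,66.66788896327715,16.172960797911568,207.86413197811532
38,197.99746788890008,-92.43603738692245,8.404179470276102
39,-42.11837132595244,170.4546457868875,129.20489864482374
40,140.6967981615314,166.06028171319312,10.31857004481833
41,-206.55031242707685,27.174953259476073,57.67578093807154
42,-65.50413575729493,-193.8414716470785,65.39404935141849
43,-203.11335303046482,-21.13990942596735,64.51210111822175
44,118.49639862264648,-177.89274430405305,-6.084917338539469
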