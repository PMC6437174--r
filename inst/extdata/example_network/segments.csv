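id,node_i,node_j,diameter_um,length_um
1,1,8,5.0711378803573,79.06329836619594
2,1,35,8.099005411748362,117.43056727792651
3,1,36,5.751663961194405,142.1613142918768
4,2,24,9.658981269353653,88.16519441641857
5,3,29,14.114245892820115,75.9398523768269
6,4,15,21.296512936598127,135.01895588936256
7,4,34,12.008650136711449,87.7432813713897
8,5,27,8.677541929503947,79.94966964604122
9,6,10,17.298568729188776,79.25910608402765
10,6,13,8.754502356723009,124.42066809999041
11,6,23,9.463963729108176,21.030888040509264
12,7,35,12.172006717417357,72.6099944984039
13,8,17,6.593133373982372,60.364176376411926
14,9,23,6.073303525749221,90.90707377543046
15,10,12,13.915799977602168,61.892815878395574
16,10,18,28.558695975014395,46.532561217548405
17,10,26,12.300803267992583,98.70360635390415
18,11,25,15.61029059539419,85.08682212317339
19,11,30,15.464301951805162,51.09777871907283
20,12,30,7.363474546430296,31.19345612715473
21,13,16,7.151113942411589,74.08447858032368
22,14,33,8.094574144277505,101.1672359061076
23,15,24,21.209551559857946,45.21528247676878
24,15,36,17.93175778735573,42.69560230962799
25,16,19,15.94216707663513,87.69535058589706
26,17,19,15.698225448384132,103.52494871262765
27,20,36,5.2392743583146455,65.97074165980747
28,21,28,8.915423103325761,42.21377341478363
29,22,28,19.21678071287769,15.502778702549515
30,22,31,20.05661946582772,91.85249656736426
31,23,31,9.18584758147251,127.44646705837803
32,25,29,7.570910612070688,41.16822427802296
33,25,33,6.567209301755605,127.55534357339562
34,27,33,4.505899428634631,91.73944505636013
35,32,36,6.098377126234479,56.05514714032519
36,2,15,18.65865528423098,114.58639807442523
37,3,25,15.740110169173679,107.17943597037757
38,7,1,9.922039228081626,127.93777380444094
39,9,6,9.197028791428657,96.14584357472546
40,14,25,10.724139730946153,141.62105551778168
41,20,32,5.683361484572948,68.42472162135657
42,26,6,7.589923533591419,111.79686144331679
43,29,30,7.42492196848166,86.02924265194265
44,8,19,13.398329912703726,117.8521185800007
45,21,31,9.755261856275787,127.14442395384681
46,5,33,8.10928621595627,94.1266480763083
47,13,19,13.712368852881946,128.74459426218354
48,24,32,9.3761708987367,117.65329007322978
49,18,23,20.724090974933794,99.34624988202813
50,23,26,4.466198267911984,126.09094692742076
51,12,18,20.465047489026624,97.28042794031174
52,11,18,28.56587489440149,129.4587379016075
53,13,37,5.363842153364054,22.00000000000003
54,35,38,8.324846075870836,21.99999999999998
55,18,39,21.859090008388065,22.00000000000001
56,5,40,11.16974169871694,22.000000000000032
57,22,41,20.11014571946702,21.99999999999999
58,34,42,12.059622310793106,21.99999999999998
59,21,43,14.803364487211507,21.999999999999993
60,1,44,18.763939435329483,22.000000000000007
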