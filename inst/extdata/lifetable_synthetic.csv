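age,sex,qx
41,F,8e-04
42,F,0.000872
43,F,0.00095048
44,F,0.0010360232
45,F,0.001129265288
46,F,0.00123089916392
47,F,0.0013416800886728
48,F,0.00146243129665335
49,F,0.00159405011335215
50,F,0.00173751462355385
51,F,0.0018938909396737
52,F,0.00206434112424433
53,F,0.00225013182542632
54,F,0.00245264368971469
55,F,0.00267338162178901
56,F,0.00291398596775002
57,F,0.00317624470484752
58,F,0.0034621067282838
59,F,0.00377369633382934
60,F,0.00411332900387398
61,F,0.00448352861422264
62,F,0.00488704618950268
63,F,0.00532688034655792
64,F,0.00580629957774813
65,F,0.00632886653974547
66,F,0.00689846452832256
67,F,0.00751932633587159
68,F,0.00819606570610003
69,F,0.00893371161964904
70,F,0.00973774566541745
71,F,0.010614142775305
72,F,0.0115694156250825
73,F,0.0126106630313399
74,F,0.0137456227041605
75,F,0.0149827287475349
76,F,0.0163311743348131
77,F,0.0178009800249463
78,F,0.0194030682271914
79,F,0.0211493443676387
80,F,0.0230527853607261
81,F,0.0251275360431915
82,F,0.0273890142870787
83,F,0.0298540255729158
84,F,0.0325408878744782
85,F,0.0354695677831813
86,F,0.0386618288836676
87,F,0.0421413934831977
88,F,0.0459341188966855
89,F,0.0500681895973872
90,F,0.054574326661152
91,F,0.0594860160606557
92,F,0.0648397575061147
93,F,0.0706753356816651
94,F,0.0770361158930149
95,F,0.0839693663233863
96,F,0.091526609292491
97,F,0.0997640041288153
98,F,0.108742764500409
99,F,0.118529613305445
100,F,0.129197278502935
101,F,0.1408250335682
41,M,0.0012
42,M,0.001308
43,M,0.00142572
44,M,0.0015540348
45,M,0.001693897932
46,M,0.00184634874588
47,M,0.0020125201330092
48,M,0.00219364694498003
49,M,0.00239107517002823
50,M,0.00260627193533077
51,M,0.00284083640951054
52,M,0.00309651168636649
53,M,0.00337519773813948
54,M,0.00367896553457203
55,M,0.00401007243268351
56,M,0.00437097895162503
57,M,0.00476436705727128
58,M,0.0051931600924257
59,M,0.00566054450074401
60,M,0.00616999350581097
61,M,0.00672529292133396
62,M,0.00733056928425402
63,M,0.00799032051983688
64,M,0.0087094493666222
65,M,0.0094932998096182
66,M,0.0103476967924838
67,M,0.0112789895038074
68,M,0.01229409855915
69,M,0.0134005674294736
70,M,0.0146066184981262
71,M,0.0159212141629575
72,M,0.0173541234376237
73,M,0.0189159945470098
74,M,0.0206184340562407
75,M,0.0224740931213024
76,M,0.0244967615022196
77,M,0.0267014700374194
78,M,0.0291046023407871
79,M,0.031724016551458
80,M,0.0345791780410892
81,M,0.0376913040647872
82,M,0.0410835214306181
83,M,0.0447810383593737
84,M,0.0488113318117174
85,M,0.0532043516747719
86,M,0.0579927433255014
87,M,0.0632120902247965
88,M,0.0689011783450282
89,M,0.0751022843960808
90,M,0.081861489991728
91,M,0.0892290240909836
92,M,0.0972596362591721
93,M,0.106013003522498
94,M,0.115554173839522
95,M,0.125954049485079
96,M,0.137289913938737
97,M,0.149646006193223
98,M,0.163114146750613
99,M,0.177794419958168
100,M,0.193795917754403
101,M,0.2112375503523
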