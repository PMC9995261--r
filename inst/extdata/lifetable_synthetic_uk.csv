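"age","sex","qx"
40,"male",0.00120653821395804
41,"male",0.00132943664721983
42,"male",0.00146485356081111
43,"male",0.0016140640918154
44,"male",0.00177847326325597
45,"male",0.0019596292143262
46,"male",0.00215923777825611
47,"male",0.00237917854508588
48,"male",0.00262152256059943
49,"male",0.00288855182807799
50,"male",0.00318278079650967
51,"male",0.00350698003759592
52,"male",0.00386420233450687
53,"male",0.00425781142804692
54,"male",0.00469151369091559
55,"male",0.00516939302832033
56,"male",0.00569594933357889
57,"male",0.00627614086082358
58,"male",0.00691543091380517
59,"male",0.00761983929043564
60,"male",0.00839599896749148
61,"male",0.00925121855924177
62,"male",0.0101935511381358
63,"male",0.0112318700655912
64,"male",0.0123759525469349
65,"male",0.0136365716972816
66,"male",0.0150255979852764
67,"male",0.0165561110099358
68,"male",0.0182425226631188
69,"male",0.0201007128373738
70,"male",0.0221481789570373
71,"male",0.0244042007406262
72,"male",0.0268900217459885
73,"male",0.029629049407712
74,"male",0.0326470754504169
75,"male",0.0359725187534297
76,"male",0.0396366929537428
77,"male",0.0436741013071124
78,"male",0.0481227615838167
79,"male",0.0530245640584191
80,"male",0.0584256659645008
81,"male",0.0643769261287013
82,"male",0.070934383876743
83,"male",0.0781597867210042
84,"male",0.0861211717985442
85,"male",0.0948935065346232
86,"male",0.104559394564448
87,"male",0.115209853560369
88,"male",0.12694517228885
89,"male",0.139875854967576
90,"male",0.154123661815132
91,"male",0.169822755591459
92,"male",0.187120964925355
93,"male",0.206181176324975
94,"male",0.227182867979057
95,"male",0.250323799791696
96,"male",0.27582187556471
97,"male",0.303917194862579
98,"male",0.33487431388113
99,"male",0.368984736609142
100,"male",0.4065696597406
40,"female",0.000748053692653985
41,"female",0.000824250721276297
42,"female",0.000908209207702888
43,"female",0.00100071973692555
44,"female",0.0011026534232187
45,"female",0.00121497011288225
46,"female",0.00133872742251879
47,"female",0.00147509069795325
48,"female",0.00162534398757164
49,"female",0.00179090213340835
50,"female",0.001973324093836
51,"female",0.00217432762330947
52,"female",0.00239580544739426
53,"female",0.00263984308538909
54,"female",0.00290873848836766
55,"female",0.00320502367755861
56,"female",0.00353148858681891
57,"female",0.00389120733371062
58,"female",0.0042875671665592
59,"female",0.0047243003600701
60,"female",0.00520551935984472
61,"female",0.0057357555067299
62,"female",0.00632000170564418
63,"female",0.00696375944066652
64,"female",0.00767309057909965
65,"female",0.0084546744523146
66,"female",0.00931587075087138
67,"female",0.0102647888261602
68,"female",0.0113103640511336
69,"female",0.0124624419591718
70,"female",0.0137318709533631
71,"female",0.0151306044591882
72,"female",0.0166718134825129
73,"female",0.0183700106327814
74,"female",0.0202411867792585
75,"female",0.0223029616271264
76,"female",0.0245747496313205
77,"female",0.0270779428104097
78,"female",0.0298361121819663
79,"female",0.0328752297162198
80,"female",0.0362239128979905
81,"female",0.0399136941997948
82,"female",0.0439793180035807
83,"female",0.0484590677670226
84,"female",0.0533951265150974
85,"female",0.0588339740514664
86,"female",0.0648268246299576
87,"female",0.0714301092074288
88,"female",0.078706006819087
89,"female",0.0867230300798972
90,"female",0.0955566703253816
91,"female",0.105290108466705
92,"female",0.11601499825372
93,"female",0.127832329321485
94,"female",0.140853378147015
95,"female",0.155200755870852
96,"female",0.17100956285012
97,"female",0.188428660814799
98,"female",0.207622074606301
99,"female",0.228770536697668
100,"female",0.252073189039172
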