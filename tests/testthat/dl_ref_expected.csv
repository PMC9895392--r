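instance,pooled_re,se_re,tau_squared
1,0.035305179478582,0.19393875506545,0.062203540286795
2,0.38873033408734,0.39418885195559,0.54215116649776
3,0.33823614528671,0.21645745719448,0.57580700462675
4,0.35460580216321,0.22951465529652,0.21530423573835
5,0.071775067338519,0.19813184320573,0.36541926190716
6,-0.54417907202588,0.19351129871126,0.1656793594185
7,0.46126394473197,0.17538897688848,0.10903542534403
8,0.67372770701482,0.49525629069483,1.6795447158757
9,0.20849697530103,0.27513695562258,0
10,0.62869024625138,0.70020588067752,1.1549852013492
11,-0.051711298343376,0.18424847186054,0.098703476874558
12,0.37546632143599,0.25315453137699,0.73426561532059
13,1.158493809742,0.2253905721507,0.12681684037141
14,-0.73060044369524,0.43529934436781,0.32607820967988
15,0.61071045174645,0.16218078558648,0.17057862852535
16,0.74091888321942,0.16500339135086,0.17704675902814
17,0.40678484848485,0.23860887816703,0.035212499999999
18,0.38295819331723,0.22905717703785,0.26591402429887
19,-0.15645860647621,0.16672951975891,0.22225532191561
20,0.24891329097059,0.15413828147016,0.25159115895734
21,0.28426473426407,0.39540607481922,0.79311495882584
22,0.2243688696137,0.27577747771465,0.20159045855823
23,0.85440949605528,0.24846098945751,0.16251124436676
24,-0.11289301469107,0.20954131019778,0.11567584498808
25,0.4788227415351,0.27245682625752,0.67896995526816
26,0.30865648466331,0.15120021181472,0.13386794530165
27,0.12653411861547,0.1479278452697,0.090697824503632
28,0.39016436723384,0.31645276615202,0.6970877324604
29,0.0024284152294007,0.25107803087929,0.20414341119663
30,0.048499979374922,0.20163754189318,0.5492615380334
31,-0.19041793162037,0.45415493603816,0.57723690518066
32,0.29011168029778,0.28001916889654,0
33,0.28827401734627,0.20824635376803,0.39051283869334
34,-0.028030567704632,0.68134025625202,2.0865520670386
35,-0.35356567196674,0.35885256527348,0.89146137622859
36,0.28043822795259,0.13304131134126,0.15146338735767
37,0.052154480098845,0.29234251642944,0.60489064614727
38,0.37062777358482,0.20319196214723,0.16225096144848
39,0.29875212361523,0.28092869819717,0.97016254327748
40,0.26562325141808,0.219006584169,0.6020804018524
41,0.61822393308603,0.21745455221242,0.55874881607142
42,0.09666804877697,0.22389579642112,0.36032862881473
43,0.025346007911603,0.33516848398609,1.0988912071426
44,0.21925108187941,0.14864846630204,0.026512521315031
45,0.356068337184,0.24624056624121,0.30222716791401
46,1.4641328711532,0.58519670584046,0.42755792
47,0.35404522610698,0.21967486292,0.47864379505301
48,-0.14611389391608,0.15112410844044,0.14935778275019
49,0.48835206925171,0.21905343024573,0.61777862931072
50,0.045086178907103,0.19351355311095,0.3551039973743
51,0.30478507584836,0.28587000205726,0.28143506494815
52,0.1984831932704,0.21151452133803,0.23464514739319
53,1.0287401363449,0.44684913885323,0.17553106899055
54,0.064854603956565,0.26333581159924,0.34560635571538
55,0.38453899807322,0.40702018810621,0
56,-0.074682895177103,0.46203007628719,0.56168919225301
57,0.22329173883204,0.17607903040642,0.23453597288439
58,0.45825705054777,0.16684671177124,0.17757209200082
59,0.62933897331357,0.35089621041248,0
60,0.19404925622304,0.27986605788496,0.50478762593084
61,0.087298034022997,0.39490248232546,0.39433932301394
62,-0.52674061488673,0.57159274352528,0.082117445
63,-0.089529351969504,0.36138657159558,0
64,0.15684940767702,0.2009266425334,0.52426125564972
65,0.28207326860993,0.13092848464972,0
66,0.42587955418523,0.21430626273632,0.41472790455272
67,0.19715991882693,0.18294262077964,0.28816730480968
68,0.70266135022598,0.19984391247287,0.51979035321392
69,0.47619075455196,0.2892033352374,0.48582697531269
70,-0.094631339730854,1.3329636335526,3.194611645
71,0.60408253532458,0.25309218249917,0.74883143365675
72,0.39931046895711,0.20866821326099,0.49822483685218
73,0.54005350097676,0.30719435438339,0.27311045535325
74,0.032535647195462,0.21586380164816,0.44702833084764
75,-0.07753649913559,0.18887214739585,0.11803003129527
76,0.26726923510201,0.35135072836378,0.97690806963583
77,-0.058642687302381,0.41272629487034,0.6386077237494
78,0.053127969175809,0.14345861521112,0.12299864556416
79,-0.14613852461856,0.31708863527603,0.50400778015178
80,-0.21277737488215,0.42200858089635,0.88455739202417
81,0.20897701828937,0.1963860970366,0.21525510328479
82,0.6062607359114,0.27148441851953,0
83,0.74379181392915,0.61716127163632,1.350978253693
84,0.10835987821704,0.23802511783625,0.51745836407559
85,0.50833846141139,0.35581489116842,1.2317376123474
86,0.15408331016404,0.13989883743186,0
87,0.48840301428153,0.2741394363806,0.73877151999653
88,-0.43416591856203,0.16715637926937,0.084685314917631
89,-0.22653711680248,0.62184818346048,0.495516125
90,0.46340618601692,0.2050155408303,0.54512856240242
91,0.38011902054519,0.27354834951888,0.80916439547004
92,0.45523909900331,0.22628226695429,0.29202074599364
93,0.28109980631406,0.58497407172504,0.51972340592043
94,0.64454419215638,0.18930100402827,0.33699519116205
95,-0.073049247384476,0.19631117954374,0.39510627961457
96,0.15929692483748,0.19334046064597,0.47300354670892
97,0.041298554465481,0.34988421446102,0.45745019927809
98,-0.047106789811319,0.18208472063509,0.29489762838152
99,0.24268664798208,0.2599781973776,0.43746415321517
100,0.37152809442005,0.26496150187593,0.51632214963061
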