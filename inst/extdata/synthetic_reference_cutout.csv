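x_cm,y_cm
2.38129697894968,0
2.38527066659747,0.104143166395661
2.39170579281737,0.209247143360802
2.40055928690187,0.316039625727248
2.41147052224177,0.425207316254356
2.42376505013645,0.537335775115748
2.43647586939668,0.652851741582758
2.44838163879551,0.771971765425766
2.45806020768336,0.894660749630944
2.46395488026854,1.02060352848261
2.46445000336997,1.14919190971153
2.45795183075591,1.27952873493487
2.44297021336656,1.41044951030942
2.41819652362428,1.54056108998909
2.38257335732998,1.66829582514007
2.33535196468464,1.79197858893221
2.27613402180089,1.90990321820318
2.20489522850817,2.02041423332431
2.12198925609826,2.12198925609826
2.02813170776905,2.2133173739765
1.92436492568385,2.29336881364602
1.81200560980809,2.3614516864325
1.692578234867,2.41725223238039
1.56773809902969,2.46085588274449
1.43918845781121,2.49274753059571
1.30859654960761,2.51379058321236
1.17751338212477,2.52518559695918
1.04730191664481,2.52841049106323
0.91907777295508,2.52514542791672
0.793665812879629,2.51718636694241
0.671574991516098,2.50635198943071
0.552992752163282,2.4943891096464
0.437799052310454,2.48288180601414
0.325598917507187,2.47316931675407
0.215771301124867,2.4662772572921
0.107531050104872,2.46286596077859
1.50827424059017e-16,2.4631987633337
-0.107717305521268,2.46713191116785
-0.216458023201018,2.47412652653997
-0.326930252289521,2.4832818084024
-0.439651478574382,2.49338743740694
-0.554899983869315,2.50299207592126
-0.67268215127273,2.51048396589456
-0.792717588295247,2.51417898277911
-0.914442870815187,2.51241113894599
-1.03703355136617,2.50362046434414
-1.15944294813571,2.48643342621304
-1.28045520630847,2.45973156570576
-1.39874926404935,2.42270479238304
-1.51296971354417,2.37488673796587
-1.62180016096168,2.31617066721146
-1.72403457935933,2.2468056074767
-1.81864231913791,2.16737351747647
-1.90482287762552,2.07874939938396
-1.98204720205435,1.98204720205435
-2.05008316337939,1.87855511193279
-2.10900383541541,1.76966434044854
-2.15917828027354,1.65679576631188
-2.20124560921657,1.54132876902447
-2.23607409088423,1.42453630426449
-2.26470795461153,1.30752974723086
-2.28830523259613,1.1912163056947
-2.30807046060339,1.0762709313407
-2.32518628709623,0.963123695159199
-2.34074801564025,0.851962603610728
-2.35570483213974,0.74275088053003
-2.37081096961936,0.635256884716353
-2.38658937557176,0.529094126484605
-2.40330961837486,0.423768328715653
-2.42098085596851,0.318728176299525
-2.43935975208202,0.213416324568585
-2.45797232319947,0.107317389273915
-2.47614788972605,3.03240658736848e-16
-2.49306263664073,-0.108849465445715
-2.50778980095342,-0.219403178089358
-2.51935322138261,-0.331679143899872
-2.52678092145758,-0.445539650792369
-2.52915554768792,-0.560700285916193
-2.5256588323847,-0.676748244494014
-2.51560776640188,-0.793168082041077
-2.49848081043304,-0.909372645882925
-2.47393319715318,-1.02473668266588
-2.44180112910832,-1.13863056619473
-2.40209540715719,-1.25045172124771
-2.35498568299081,-1.35965161801246
-2.30077707477572,-1.46575665108727
-2.23988128443812,-1.56838176005842
-2.17278458689647,-1.66723625259038
-2.10001511644589,-1.76212190967646
-2.02211175702932,-1.85292404031311
-1.93959666698242,-1.93959666698242
-1.85295306142563,-2.02214342801612
-1.7626093717809,-2.10059605116012
-1.66893034274029,-2.17499236816371
-1.57221505599164,-2.2453557983844
-1.47270133022352,-2.31167803745359
-1.3705754778895,-2.37390636331261
-1.26598603398744,-2.43193654428499
-1.15905983504841,-2.48561183754599
-1.0499187316199,-2.53472804126631
-0.93869526754979,-2.57904405134196
-0.82554584589887,-2.6182969139654
-0.710660205502012,-2.65221999385085
-0.594266426419451,-2.68056262309108
-0.476631132531967,-2.70310947659234
-0.35805502719759,-2.71969794541801
-0.238864344123016,-2.73023194659086
-0.119399183406698,-2.73469090342113
-5.02068392669948e-16,-2.733133030789
0.119006306088174,-2.72569253342838
0.237319197055421,-2.71257083479276
0.354674785317885,-2.69402245925824
0.470852399156998,-2.67033665106247
0.585676549553595,-2.64181619246686
0.699013835722868,-2.60875515011134
0.810764794987136,-2.57141740972027
0.920851186900043,-2.53001784268586
1.0291996619549,-2.48470778228133
1.13572316282198,-2.43556618245474
1.24030170599188,-2.38259740926225
1.34276436591209,-2.32573610435274
1.44287431325748,-2.26485899911357
1.54031863568664,-2.19980298930361
1.63470439672764,-2.13038824691054
1.72556198136402,-2.05644469053455
1.812356261296,-1.97783979491845
1.89450552371488,-1.89450552371488
1.97140748651232,-1.80646213658257
2.04247111579412,-1.71383675995309
2.10715241465812,-1.61687491555221
2.16499190897441,-1.51594365482691
2.21565125394525,-1.41152552220935
2.25894625322771,-1.30420322738592
2.29487363789044,-1.19463560106558
2.32362920019186,-1.08352609076204
2.34561530836722,-0.971585672835653
2.36143642128704,-0.859492567460588
2.37188194187685,-0.747851503637703
2.37789655136679,-0.637155460623482
2.38053900126606,-0.52775279079404
2.38093115097955,-0.419822401126954
2.38019977050243,-0.313359244543592
2.37941422749906,-0.208171770738462
2.37952360135197,-0.103892244108086
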