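# Synthetic regional brain TACs (kBq/cm3, decay-corrected): 12 gray-matter
# regions x 34 frames over 123 min, generated by the package cohort
# generator (noiseless, seed 20). Not subject data.
frame_start_min,frame_end_min,CERCX,CAU,PUT,THA,LFC,LTC,HIP,LOC,LPC,ACC,PCC,AMG
0,0.333333333333333,0.0401170433722159,0.0200923392080003,0.0274231299524549,0.0264499033427796,0.0306785629471333,0.0299508773785228,0.0283537540595228,0.023517137248024,0.0347475963637149,0.024680831088068,0.0330213762645478,0.0212992983312579
0.333333333333333,0.666666666666667,0.271367631242104,0.139093530998427,0.189347137174361,0.181226131562467,0.212090224125638,0.205475093290796,0.1941445314314,0.162013252999466,0.239486974468225,0.17000145369642,0.222985711094612,0.145812783931632
0.666666666666667,1,0.71309474488306,0.37354069314963,0.507300638814997,0.481480872691975,0.56891651452719,0.547042775564311,0.515295330705173,0.432979394010259,0.640363576244256,0.454200263094983,0.58513085967592,0.387297294387758
1,1.33333333333333,1.28284698430018,0.686666004992398,0.930484259670133,0.874751012505054,1.04475381027675,0.996842134455679,0.934891146488346,0.791865701065698,1.17189182445587,0.83034455291021,1.05136375639111,0.703879739167034
1.33333333333333,1.66666666666667,1.7188248823135,0.944491165276123,1.27664307732037,1.18460553271922,1.43550878500516,1.35647425854159,1.26324086787153,1.08208841390429,1.60286828705646,1.13395629316199,1.40690453876517,0.95435666109736
1.66666666666667,2,1.98160136801658,1.11704129754853,1.50664184035784,1.37677919498714,1.69650893102336,1.58724659737484,1.46359100337139,1.27090184739283,1.88471941140395,1.33068478212133,1.62064436256274,1.11204545989695
2,2.33333333333333,2.11548913632288,1.21939303572094,1.64229061208413,1.47594399370634,1.851446836531,1.71621111445181,1.56274576566538,1.37793989202976,2.04617728611102,1.44127985081212,1.72968545696205,1.19707007799849
2.33333333333333,2.66666666666667,2.22199124447531,1.30016276578863,1.75032428079131,1.54881949845082,1.97466644687162,1.81766778969771,1.63272545965363,1.46108127070245,2.17252836142759,1.52667487836474,1.81748692071473,1.26285832819459
2.66666666666667,3,2.32153780353227,1.3713625740917,1.84682147987328,1.61154055914642,2.08421016449516,1.9088700015271,1.69124280103168,1.53432902314124,2.28434973976989,1.60172428333565,1.90036858410848,1.32185777890783
3,4,2.50307127782364,1.49181065321904,2.01343375995282,1.71600984772043,2.27163963982766,2.06838929552106,1.78541975780255,1.65870605036698,2.47527924044348,1.72924842899889,2.05297233925171,1.42554686153682
4,5,2.76037945426834,1.6502151904701,2.23733465694921,1.85730941241868,2.52029546620499,2.28730844313738,1.91212595627017,1.82442964982179,2.73040001654075,1.90071029684799,2.27053708367775,1.57053348344872
5,6,2.9922217191044,1.78703667878143,2.4344855919974,1.98370090414165,2.73596359629449,2.48303601383377,2.02755538764335,1.96899148421179,2.95347308428159,2.05287315067269,2.46764652844653,1.70318753801552
6,9,3.37268665928016,2.00680469250945,2.75812023071804,2.1942079231421,3.08202007022767,2.80731050638889,2.23107556676558,2.20165575989927,3.31402030030682,2.3061586102337,2.79476963820002,1.92990241217071
9,12,3.80907520645925,2.253806949083,3.13300900564228,2.43794368667564,3.46951965640949,3.18513170435129,2.49003347376743,2.46115390754774,3.71957681562047,2.603839535602,3.17753609526364,2.20450520006701
12,15,4.14301299762855,2.43747720755366,3.422775711698,2.6255489906585,3.75609456052191,3.47917519747242,2.71527256509298,2.65172765982488,4.02091596906199,2.83784089432257,3.47815337306224,2.42833523942484
15,18,4.40220924283347,2.57601593375368,3.65163938287956,2.76892461641883,3.97167787784943,3.71223079352075,2.90811772784076,2.79271597890256,4.24750589464698,3.02403368760219,3.71852167473786,2.61379254021558
18,21,4.59099972067556,2.67213533896955,3.82291244117622,2.8683098729045,4.12137442219375,3.88723064954448,3.06309512196399,2.8872071336139,4.40399885134206,3.16351368388438,3.90160108542466,2.76151374128447
21,27,4.77910047159709,2.7589385825924,4.00009356578949,2.95982116700942,4.25659487087607,4.06998689121825,3.24510839902506,2.96718373200131,4.54459457020954,3.30892283330918,4.09772775857157,2.93091721695984
27,33,4.92841438490916,2.81579499060187,4.15115108472734,3.02194739233467,4.34512629356573,4.22786493804187,3.43142056433837,3.01117628098946,4.63525244720798,3.43434308229869,4.27355846717922,3.09887190419022
33,39,4.98367578779027,2.81938050525883,4.22233142565302,3.0284805600784,4.35101681961812,4.30487495492488,3.55923760498493,2.99922269868059,4.63846184872736,3.494716623271,4.36809313676596,3.21000728234744
39,45,4.96876805569527,2.78467982290251,4.23312651579116,2.9943634953848,4.29761750834742,4.32040558970319,3.63921421570247,2.94778437850243,4.57888931740577,3.50554496694714,4.40006634448974,3.27588276341721
45,51,4.89630766782543,2.71934476275646,4.19361730348711,2.92747787599807,4.19684220283615,4.28458237245847,3.67693499616262,2.86525316292451,4.46919961588861,3.47493286513563,4.37936391934726,3.30243622895608
51,57,4.78471290068125,2.63446431743836,4.11883364757273,2.83971324872178,4.06577322491823,4.21259368501752,3.68305660148055,2.76371648720699,4.3276753099343,3.41529597158396,4.32089459326985,3.29938996803838
57,63,4.64163966468741,2.53451383217433,4.01527717295746,2.7353839911925,3.91143077579713,4.1109027449339,3.66100287410878,2.64782795020038,4.16162476520657,3.33172273251279,4.23102475313228,3.27077147813608
63,69,4.47929352988829,2.42647154621061,3.89289225510442,2.62230243378809,3.7445275877923,3.98969275035024,3.61864994310431,2.52512550908008,3.98260252083533,3.23257398168122,4.11994385618956,3.22346428259561
69,75,4.30704198676571,2.3157625291299,3.75977036144609,2.50594264330851,3.57348797918869,3.8570706075845,3.56151322597178,2.4012423446222,3.79944803822262,3.12435775930463,3.99570351743274,3.16299485877207
75,81,4.12633594650708,2.20286979441873,3.61738132018075,2.38667995489486,3.39911915790707,3.71452964945487,3.49043793322266,2.27643830929548,3.61291842097953,3.00817989048691,3.85992645858851,3.09059592939292
81,87,3.93829221827997,2.08811721088946,3.4668619539494,2.26492967279095,3.22191887582263,3.56326520022277,3.4065759066063,2.15085737031598,3.42351929905923,2.88499802880088,3.71392812937696,3.00735785450024
87,93,3.74420095562557,1.97196056474319,3.30945059537321,2.14127502425102,3.04258136560208,3.4045834515309,3.31124587081907,2.02482550066309,3.23198313008323,2.75587138140941,3.559136707965,2.91445101238997
93,99,3.55121238920807,1.85834914416583,3.15105766316927,2.02029572172648,2.86713230895809,3.24459462765572,3.20987279029635,1.90257847527161,3.04484975725615,2.62585871043077,3.40177051042408,2.81635733632652
99,105,3.36455617140148,1.75022392273478,2.99635839193159,1.90491050524302,2.70014517164688,3.08798993878744,3.10596324505375,1.78710424935334,2.86688454658739,2.49871216825204,3.24656207719066,2.71655883720667
105,111,3.18350768437669,1.64683056673789,2.84501866574789,1.79422265418894,2.54050010363244,2.93445345232058,2.99940991446579,1.67738626969593,2.69681454581102,2.37409262151453,3.0933615520355,2.61523366522315
111,117,3.00732582999281,1.54745909319796,2.69662518602813,1.68754083220267,2.38709644295485,2.78361441971577,2.89041257504724,1.57251029673414,2.53344995426842,2.25169054089703,2.94193984890387,2.51252038674165
117,123,2.83521118907852,1.4514185704727,2.55069573590166,1.58417257334018,2.23886346595639,2.63502140168109,2.77906335337863,1.47160762596844,2.37563173566195,2.13113210642945,2.79196607001671,2.40845805762999
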