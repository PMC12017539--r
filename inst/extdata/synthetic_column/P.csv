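"","VIP1","E23","PV23","SST23","VIP23","E4","PV4","SST4","VIP4","E5","PV5","SST5","VIP5","E6","PV6","SST6","VIP6"
"VIP1",0.0773814915167168,0.0177157249581069,0.0100220068264753,0.08,0.0343292831070721,0.013609074074775,0.0193163254763931,0.0172445623856038,0.0132838789094239,0.0461628773715347,0.0239299353491515,0.08,0.0386649986729026,0.0295705620385706,0.0156761815119535,0.0122197018191218,0.047737889662385
"E23",0.0484501381963491,0.1,0.15,0.1,0.08,0.0463782473560423,0.0213471411261708,0.0132896074932069,0.0175897524598986,0.08,0.0392177460435778,0.0167515870090574,0.0281169902998954,0.05,0.0468700856808573,0.0278325627185404,0.0309363876003772
"PV23",0.0350749118626118,0.2,0.15,0.110683467546478,0.0600854123895988,0.0192248013429344,0.0279090254381299,0.015863214218989,0.0257196588907391,0.0233423227164894,0.0333938483241945,0.0320508138649166,0.0404425054788589,0.0114275509957224,0.0326070444099605,0.0466983191203326,0.0345181729178876
"SST23",0.0364505706913769,0.15,0.1,0.110553107969463,0.1,0.0268411735538393,0.0241204483341426,0.0187575844116509,0.0225687068607658,0.0460488568525761,0.0356128584314138,0.013058864781633,0.017632553614676,0.026365843648091,0.0381082114111632,0.0352305582445115,0.0477834256645292
"VIP23",0.0127188762184232,0.0723663251381367,0.100726479068398,0.15,0.106344196451828,0.0442585793230683,0.0206394387502223,0.0490754713956267,0.0214061790890992,0.0306583363935351,0.0406579849496484,0.0464615922234952,0.0203731265943497,0.0100992810260504,0.0442671311460435,0.0413209537789226,0.035240537924692
"E4",0.0264247902110219,0.12,0.0457802650239319,0.0273139134421945,0.0261872013937682,0.1,0.15,0.1,0.08,0.06,0.0390591669641435,0.0356620482169092,0.0344808989856392,0.06,0.0206397103518248,0.0441291622817516,0.0452470210473985
"PV4",0.0462938455864787,0.0497784299962223,0.0158004890754819,0.0164384911488742,0.0293251130823046,0.2,0.15,0.0832624462014064,0.110402157884091,0.0447187518607825,0.0434841404855251,0.0336976169142872,0.0382678558304906,0.03929906161502,0.0449598528351635,0.0338902549166232,0.0232367809023708
"SST4",0.0459358449280262,0.0268507098220289,0.0133380954805762,0.0279061872512102,0.0212835488654673,0.15,0.1,0.0705364904785529,0.1,0.0229020667262375,0.0318810461740941,0.0217333848774433,0.0189517621975392,0.0225158923119307,0.0395986377261579,0.0238439579401165,0.0439700465556234
"VIP4",0.0180185408890247,0.0429126400966197,0.0283307168353349,0.0344111571460962,0.0119662751536816,0.0776735816476867,0.102868018769659,0.15,0.0619522811751813,0.0249639405775815,0.0338482847623527,0.0337149088922888,0.0496215016022325,0.0127185779530555,0.0324615845549852,0.0327221219334751,0.0276790792122483
"E5",0.0319958918448538,0.02,0.1,0.08,0.0440990262106061,0.02,0.1,0.08,0.0400594330672175,0.1,0.15,0.1,0.08,0.02,0.1,0.08,0.0471525880042464
"PV5",0.0286575379502028,0.0464764413516969,0.0302089279517531,0.0180410030856729,0.0441991885192692,0.0161911641899496,0.0221925560105592,0.0205244465824217,0.0296394976880401,0.2,0.15,0.0938266521692276,0.0998349300166592,0.043055103784427,0.0224109494313598,0.0316776442248374,0.0129947472177446
"SST5",0.0257622960489243,0.0360436550248414,0.0208109346684068,0.0422121453471482,0.0248045187443495,0.0352591009996831,0.0260810188855976,0.0145225539710373,0.0256286340113729,0.15,0.1,0.0898951735161245,0.1,0.0136015550047159,0.0192486264556646,0.0356668333522975,0.0447825702000409
"VIP5",0.0343421724066138,0.0154594781808555,0.0420313996169716,0.0401067232713103,0.0351215483527631,0.0163109018560499,0.0386442855838686,0.046475207740441,0.046858998965472,0.08409511806909,0.114902602401562,0.15,0.118452874752693,0.0126432611048222,0.0435616846289486,0.0227244057506323,0.0232890703994781
"E6",0.0412891968339682,0.0330916018970311,0.06,0.0221766523551196,0.0110205210745335,0.0399645585101098,0.06,0.0306182517297566,0.0354554746393114,0.011753284195438,0.06,0.01003831602633,0.0130567709542811,0.1,0.15,0.1,0.08
"PV6",0.0457124868780375,0.0498635359574109,0.010247882110998,0.0124236590415239,0.0191384035348892,0.0454154767654836,0.0201272337324917,0.0178562847152352,0.0328104149457067,0.013050691485405,0.0119431951921433,0.0215535697713494,0.049655102211982,0.2,0.15,0.0758953726105392,0.0830079516721889
"SST6",0.0348279919661581,0.0173413795605302,0.0197927209734917,0.0477117251977325,0.0498425909224898,0.0333117501810193,0.0232540803030133,0.0140030649956316,0.0293044656701386,0.0493690982181579,0.0404565951228142,0.0154046371765435,0.0480064877122641,0.15,0.1,0.0830130698299035,0.1
"VIP6",0.0332494140509516,0.0413226382341236,0.0338787335529923,0.0451141598355025,0.045375357484445,0.0393910126388073,0.0490744571667165,0.010783621519804,0.0423307948186994,0.0470093333721161,0.0187703196890652,0.0421284172032028,0.0231472552195191,0.0619609409244731,0.0751142449351028,0.15,0.0616540018608794
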