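"","VIP1","E23","PV23","SST23","VIP23","E4","PV4","SST4","VIP4","E5","PV5","SST5","VIP5","E6","PV6","SST6","VIP6"
"VIP1",NA,0.281552333664149,0.281780729908496,0.8,0.314621764328331,0.162858870252967,0.353625872638077,0.460022594034672,0.367726195044816,0.232766713667661,0.473907589912415,0.8,0.471484968718141,0.190192336961627,0.373034203331918,0.445286764856428,0.446237751562148
"E23",0.118175958283246,0.5,1,0.8,0.6,0.195488572586328,0.495784098189324,0.152552602626383,0.452887259516865,0.6,0.297898908704519,0.331783304642886,0.47273011058569,0.4,0.158591038733721,0.207495779450983,0.100621109735221
"PV23",0.436484899371862,1.5,1,0.158089115470648,0.142732136324048,0.465634788945317,0.329936724249274,0.36491826782003,0.24042017608881,0.488080685213208,0.247600660473108,0.333575666230172,0.238963572308421,0.294531727489084,0.149551275372505,0.258797086868435,0.182248178031296
"SST23",0.270455513801426,1,0.8,0.485914768185467,0.8,0.311975892167538,0.43688042704016,0.468727992381901,0.493441563658416,0.264338215906173,0.330505817756057,0.376903181523085,0.281639938242733,0.419602361135185,0.216951809544116,0.346350595261902,0.160948580224067
"VIP23",0.220298163313419,0.275206408556551,0.238634999468923,1.2,0.210170775931329,0.352840173896402,0.121901934035122,0.310066222026944,0.103364234417677,0.355501217953861,0.300038294587284,0.275268605910242,0.310497275087982,0.221714427601546,0.284466920979321,0.106426950450987,0.159299806319177
"E4",0.349189184140414,1,0.309202176146209,0.457485742960125,0.252797623723745,0.5,1,0.8,0.6,0.5,0.497545425314456,0.407325153145939,0.15617172177881,0.5,0.170231273025274,0.126833485532552,0.108500081300735
"PV4",0.358524244930595,0.138835416175425,0.209898758959025,0.157705431524664,0.121056737657636,1.5,1,0.225042549986392,0.327080441918224,0.23157115150243,0.166634191758931,0.19848042530939,0.474647477362305,0.12944931704551,0.420100376103073,0.129943159408867,0.44357267152518
"SST4",0.314982246980071,0.384380566608161,0.12929061325267,0.27690247753635,0.43121916083619,1,0.8,0.410030457656831,0.8,0.250139222573489,0.107922160997987,0.288932839874178,0.223132209666073,0.481673442199826,0.195228144247085,0.106711099576205,0.410805435851216
"VIP4",0.402400803659111,0.238264652807266,0.301548027712852,0.195253547932953,0.372382181417197,0.366941920202225,0.181803452689201,1.2,0.222990550007671,0.357019184343517,0.456802565138787,0.411784936673939,0.486981149110943,0.49429177083075,0.122899247147143,0.323624573089182,0.236642935406417
"E5",0.434077284485102,0.2,1.2,1,0.128847534302622,0.2,1.2,1,0.243529805075377,0.5,1,0.8,0.6,0.2,1.2,1,0.416740151681006
"PV5",0.154603123571724,0.217690944299102,0.276430865004659,0.453266613744199,0.248690203856677,0.355614007357508,0.266793715022504,0.29508816935122,0.396305742952973,1.5,1,0.352766768075526,0.221751585975289,0.362692445423454,0.274989977572113,0.290933344326913,0.278577961586416
"SST5",0.237555641308427,0.499445988610387,0.490814563538879,0.397320172097534,0.194439715798944,0.346911611221731,0.147916979528964,0.474821486696601,0.209894600324333,1,0.8,0.450712745450437,0.8,0.250036787241697,0.472536945156753,0.188352616410702,0.440187973994762
"VIP5",0.418275304418057,0.226517396606505,0.162701471615583,0.39776160903275,0.303587860893458,0.428885979298502,0.26595621490851,0.393588057439774,0.483662308286876,0.31390993501991,0.352196918893605,1.2,0.450529444590211,0.302435390371829,0.35256327027455,0.23392000393942,0.304779373854399
"E6",0.493001450318843,0.132132454682142,0.8,0.43162954710424,0.240310169477016,0.220084922201931,0.8,0.133178049698472,0.337251003365964,0.467527628876269,0.8,0.280658972170204,0.174788617063314,0.5,1,0.8,0.6
"PV6",0.412299946695566,0.238681863620877,0.333387001976371,0.496676408220083,0.140270570944995,0.248267303220928,0.379090420622379,0.313423236925155,0.364678490255028,0.161524596437812,0.104243222810328,0.382953034620732,0.108646115660667,1.5,1,0.402514289692044,0.173308439273387
"SST6",0.199198345001787,0.167950411140919,0.374639810062945,0.37474821144715,0.356937937252224,0.315722062438726,0.254047711752355,0.430561269447208,0.409321365132928,0.29644518289715,0.343856223952025,0.210506858862937,0.146204343810678,1,0.8,0.179227741621435,0.8
"VIP6",0.285368823166937,0.122628823574632,0.432610875926912,0.444715915527195,0.370971397310495,0.391043502278626,0.448244643770158,0.341534077189863,0.4502461431548,0.36209235265851,0.474196961615235,0.171855653077364,0.459516559541225,0.100423524901271,0.484407558105886,1.2,0.147640971746296
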