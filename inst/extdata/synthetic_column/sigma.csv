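"","VIP1","E23","PV23","SST23","VIP23","E4","PV4","SST4","VIP4","E5","PV5","SST5","VIP5","E6","PV6","SST6","VIP6"
"VIP1",157.949533849023,297.947362193372,188.28546757577,141.528551245574,128.487877675798,130.249046499375,234.308689204045,122.40932044806,112.243790773209,130.811163177714,210.488368943334,249.314862664323,211.930035275873,183.68235033704,63.1556693231687,183.551400504075,159.22012059018
"E23",279.991277912632,272.465472354088,266.003468434792,167.333001631778,164.269503974356,268.097139790189,95.2774226432666,249.227155535482,62.4629946076311,69.042419444304,153.743014566135,105.236809595954,244.516850635409,123.363322997466,277.110931475181,176.163683831692,213.641533174086
"PV23",273.306486266665,79.1214459575713,149.146879685577,75.5180585663766,268.172511202283,192.350785783492,70.0148244621232,186.904755025171,200.948631460778,225.596287415829,265.752161631826,113.120778417215,282.988211966585,72.8295589913614,76.9935153191909,83.580616931431,86.8709770846181
"SST23",116.413972352166,215.654818410985,255.032308120281,236.539039481431,112.48162232805,253.817909408826,108.406547410414,270.111228700262,161.56697612023,51.9602299435064,99.1185719729401,286.385504307691,164.176042028703,242.717203870416,188.388122082688,147.032193327323,95.6179777393118
"VIP23",106.422354478855,114.827641181182,78.2609544228762,204.811754531693,53.381626913324,255.955931218341,254.821908322629,99.2863986873999,74.6128960861824,122.133301058784,166.112219926436,147.097515419591,183.280958805699,87.3779161018319,88.2671025581658,254.848611436319,183.885313291103
"E4",224.859079241287,279.595259646885,153.143221640494,108.966094744392,174.738383688964,292.158282489982,299.141636129934,150.079709780402,275.828623748384,232.395902345888,115.376476908568,119.271445157938,102.288145176135,97.2599045024253,198.45368283568,134.382474771701,196.553089900408
"PV4",248.115119594149,209.203418181278,115.053190744948,50.4513692110777,249.586154718418,110.355992114637,98.1663852115162,150.408779690042,229.751594783738,94.0173308015801,290.765673399437,218.381100113038,150.197473482694,139.239297260065,225.072101352271,57.5850711436942,60.8906353707425
"SST4",103.592162730638,175.635027710814,233.1342507503,78.8092758273706,236.25723477453,177.723692974541,277.411820436828,258.372096531093,282.930669677444,101.315751974471,121.184223110322,221.315644285642,161.402452923357,197.252809256315,153.560058574658,198.136517265812,226.781131653115
"VIP4",58.3072378183715,286.008080479223,253.390459355433,64.3060390255414,94.7577026789077,255.404045118485,287.509979633614,156.086225365289,160.393986222334,85.6495568994433,199.569270957727,284.286305378191,66.1108477623202,170.34421262797,236.723852355499,275.83141218638,147.63990616193
"E5",68.0434740032069,150.341699202545,271.167687966954,93.7428388977423,222.757417487446,180.070958228316,88.5396124329418,148.717626766302,253.740491124336,123.671160265803,132.197848241776,274.592437152751,77.7135868673213,129.225139226764,156.104636855889,76.0540748131461,262.697842041962
"PV5",197.030913329218,194.009778974578,227.681323257275,114.425882592332,215.896118618548,58.7507387506776,56.1989829991944,141.638009937014,292.643416509964,162.994951952714,157.991485216189,138.50457140943,79.2462667566724,141.940081736539,282.189934293274,205.132777988911,256.216489837971
"SST5",83.6447586887516,71.3703038170934,114.257634745445,234.861121815629,282.985370443203,290.342847886495,170.026771153789,139.872945914976,182.961377850734,174.716756283306,187.068834155798,196.387724555098,119.832000648603,95.1493058353662,209.734672633931,269.06288532773,218.855529278517
"VIP5",234.589233016595,136.646457843017,174.404669157229,83.1889849039726,174.779238540214,224.928338150494,202.415138436481,287.372943549417,181.7257626215,194.035512290429,250.400110159535,108.970895595849,112.374854634982,184.003757149912,117.800507880747,232.726532279048,223.075074853841
"E6",169.570720824413,212.213988602161,98.77305572154,143.824006442446,137.166157842148,270.091677561868,246.164299850352,142.761427804362,78.6735239787959,132.146196975373,124.002256733365,195.814234856516,192.079708282836,146.694568288513,77.8244125656784,137.071242101956,224.251165182795
"PV6",97.7115005487576,236.614498670679,81.499603879638,274.167834967375,68.5468689887784,242.980558902491,161.121772206388,235.67117798375,216.049664316233,147.417488403153,173.321822436992,73.0820203432813,158.38655004045,104.102342168335,90.1426153257489,234.961249935441,181.088702939451
"SST6",154.625683219638,97.2944552311674,52.9177583637647,256.662750220858,176.796351163648,202.428238012362,69.583671411965,283.261798217427,87.128605239559,123.357649438549,153.536785056349,289.996994263493,213.666716543958,244.226478459314,243.612569011748,51.7960188561119,181.745500024408
"VIP6",214.268637716305,239.286471577361,238.439491030294,124.715228867717,249.097253847867,131.316445721313,260.003265005071,60.6700393953361,228.89828258194,163.564820785541,92.0926313381642,211.49837244302,244.871910964139,178.552042762749,141.070958646014,73.5207690275274,293.697347585112
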