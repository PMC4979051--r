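probe_id	A001	A002	A003	B001	B002	B003
g00001_p01	464.26090397849	501.880487524076	548.312267920435	453.401151660703	507.842531094845	425.567867001681
g00001_p02	561.275823586876	649.107900958868	611.8491028082	593.885406682826	482.981431985242	575.108120792897
g00001_p03	513.330214137922	412.447042454745	571.47014034603	461.129843359315	549.911354054771	413.872843464424
g00002_p01	130.229300816738	137.643505512849	137.424732023333	160.059258814654	98.9830218612284	123.314247535433
g00002_p02	159.143018215224	156.06307957474	145.751740745421	128.558352311203	173.019663129387	121.666549124372
g00002_p03	70.654657067343	50.0630146249923	55.2438628381438	54.6042201398148	53.2632895018578	62.7188064793216
g00003_p01	95.1488978168446	150.952275634733	154.187954171568	105.323015378107	113.317651302904	107.233289466936
g00003_p02	110.833297060413	119.288018674175	139.444523143809	135.438640247498	102.844710225225	91.8229023264715
g00003_p03	196.589674698147	114.753758434874	168.490456864875	149.35488193905	164.978503226146	236.164356130544
g00004_p01	123.570001325939	129.616617126801	142.401892479107	176.870987803961	122.778430344411	127.322180115706
g00004_p02	125.55615132614	116.745408290521	105.479176881545	136.081320080252	115.724431624496	124.710158867692
g00004_p03	147.602020763085	107.927911837397	132.803643543489	127.72281429043	135.422686390788	160.35019678197
g00005_p01	75.1169999003733	118.207571298771	143.27715729123	73.4922224956629	94.6952096161077	72.9353377402248
g00005_p02	141.517704943572	188.751173973409	232.88211517976	154.679894022824	219.604983225407	154.941060206969
g00005_p03	82.1542861670755	66.4390259409585	75.3213155582463	79.1200569871271	52.5790859388325	54.5923116999686
g00006_p01	135.798935852322	86.837520285865	141.102579230458	108.99368160028	92.6384240427483	118.075790706
g00006_p02	132.132241531667	121.253775307863	169.668392245772	166.27438020395	158.477730608149	123.845435397068
g00006_p03	219.503373455402	197.179315132055	311.248583058642	171.164156297616	192.409201832315	204.076139448452
g00007_p01	212.021074025198	161.845877720191	239.536095710661	167.239908914876	262.110054260578	203.939187960604
g00007_p02	184.837290216423	222.954560424491	137.824654983182	133.534227860886	163.204762989032	195.903880187552
g00007_p03	125.675523096298	119.130184450591	96.5288543540849	78.7690975671122	138.910742933274	127.278498164358
g00008_p01	161.697411738615	117.762301673537	135.23269798175	154.580239509654	242.665230220042	181.100877817662
g00008_p02	93.6674486558131	127.609415490413	90.1657790711823	148.185184678988	138.782734163952	89.4392012776461
g00008_p03	281.674857546864	263.442358294709	272.257517881196	428.905607514688	375.183190429833	296.805970628192
g00009_p01	260.0404952259	194.097469993548	247.821920304798	234.919856269401	311.652783168138	219.550078672264
g00009_p02	202.489608229082	175.515880260575	184.031162475601	194.635721516097	186.376383763715	244.690274319499
g00009_p03	148.403466473566	148.94041586952	262.864390193658	242.157472239628	162.731305539185	206.126769048154
g00010_p01	276.802766596779	533.366430562877	385.205796203836	484.942934322284	418.086691998441	425.79871043255
g00010_p02	713.84977041339	585.965126560541	897.413562407837	639.942043624409	433.725179888316	596.105350641103
g00010_p03	912.595548199267	724.714607239511	584.83574731762	553.011851138076	811.705656599077	714.53422905428
g00011_p01	251.87387813339	308.980025533325	324.632185574524	492.613573895201	434.076774768866	315.81972515876
g00011_p02	209.816920832603	251.081476480202	128.365526141223	216.47726974974	235.871397503283	334.873528216733
g00011_p03	290.709468472885	206.402439889503	277.336531069424	398.74310132377	479.252509369534	437.973282025951
g00012_p01	512.267929451778	442.051223105648	422.328926828744	400.838765597162	366.313429973618	482.078516172036
g00012_p02	1823.68854324994	1409.86133915605	1169.46491896544	967.087536795634	1494.22687174194	1917.50318860331
g00012_p03	1358.18961149089	1318.84996325253	857.812948171342	1092.53813947667	1274.61889601759	1255.11037537887
g00013_p01	551.992769910506	570.283735485876	546.46318801545	974.819128488889	518.705082677094	614.651254260632
g00013_p02	497.87266187128	297.618684829698	357.864651751164	335.718025665266	223.713852115839	321.0730388639
g00013_p03	1836.83674012928	1194.73109928555	1096.99294176882	733.437522911591	1322.82713076957	1838.23712985619
g00014_p01	280.870393683343	185.0393717753	226.779028364614	316.412633207281	313.161519092666	313.77960202436
g00014_p02	194.040936162166	273.821467448298	186.60284582738	266.848076469172	359.416467036721	272.37893434238
g00014_p03	233.593920657648	197.600027486257	195.773191323542	357.098762703901	262.445184140473	294.111238682406
g00015_p01	784.119661450819	1288.2673727298	693.695347213899	776.8807271463	1085.68844270592	1032.59476853825
g00015_p02	695.984640635741	500.426014788895	796.665640908891	599.073985789063	599.353537268976	746.398840642878
g00015_p03	551.489351166733	498.859224349242	481.708935985146	575.308990521412	434.321913648962	371.473390498077
g00016_p01	154.644893979938	154.372473653993	182.860263946525	336.966070649959	220.070525538738	229.301183028108
g00016_p02	234.962566848746	316.104763601118	335.805110458389	323.185278637579	335.691449952925	199.992259443967
g00016_p03	122.717009137154	134.268154788555	218.166466278722	131.758785286837	200.072443537311	219.094510848338
g00017_p01	116.816206076208	51.0193820322966	117.919269486273	148.551257857711	113.566297863219	156.130387410822
g00017_p02	97.4711890050504	79.0026327440718	146.436300061609	147.280410553093	131.168054907771	132.979179972703
g00017_p03	70.582685525296	83.1917553444968	51.5429577004526	105.4247043175	119.444727106457	103.057433715242
g00018_p01	104.651283444095	98.9707114225791	121.699099067005	125.517056407303	125.377702592684	137.715029743688
g00018_p02	80.7385833923599	66.7599221027981	95.02041517153	61.7141961273372	53.8966443615925	60.2882888047523
g00018_p03	90.6139580965974	94.8514659447929	116.661168763662	120.314388481818	123.122970060348	91.4655468120996
g00019_p01	149.646277205302	214.3448452391	119.563879190271	159.956118145475	129.355812011824	203.714002593164
g00019_p02	134.484525179716	150.316895614224	140.598448672728	180.918743266419	204.19370839445	180.293346035519
g00019_p03	465.813689336386	422.83499068574	306.738829068882	291.01275761208	305.45463390975	374.593055522441
g00020_p01	268.426158592572	154.653734928788	144.873037242146	134.1352826693	157.425544182475	172.61583882128
g00020_p02	217.456498778343	134.86544612737	160.938908348521	285.084490791422	255.429065374751	163.166486897085
g00020_p03	241.357194121587	418.158200277648	379.695234279368	261.845386531388	273.800426847472	211.761891543629
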