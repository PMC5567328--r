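lat	lon	x	y
-56.507472793123235	113.127502273794164	8562096.975757930	-6683557.419143019
24.624717165867196	-131.485877416393208	-11892448.584798818	3181950.285420050
-5.760761398746624	41.582978769192124	3896844.049036704	-757769.777263273
-22.791907228983547	-34.979948809353374	-3181136.517573041	-2953189.591664596
-25.534549161501388	95.773082927861822	8637446.793308733	-3294760.792212139
51.131211270174646	-155.622830176605390	-12293498.832195703	6176692.691469423
71.305315255182620	38.453177172313218	2491568.368814540	7816989.546122092
-56.785838239143438	128.548328395192868	9706011.209504079	-6708589.492334314
26.890125272583219	46.205230450712605	4148383.962100476	3461862.406493669
-35.498712945419811	-64.318429636732532	-5577788.237871259	-4491610.819467071
82.185347228580724	56.086580131880112	3085805.311751596	8325438.832863804
73.893628254560952	-58.264976615036119	-3648060.503424493	7967147.212115128
23.913261529458637	60.693403827632437	5501452.111184496	3093384.544372134
44.480849085919232	-133.796015480860746	-11054979.408830227	5494230.588157781
2.667050552733912	-79.202972089478635	-7434075.027956035	351103.234005895
57.357565474100312	-168.221383849110481	-12638633.615942203	6759607.913434067
-9.085024009581844	-149.792619973431300	-13995312.053334774	-1193237.482941603
-28.369008216777914	19.717063133942361	1761051.107516184	-3642761.777255616
-39.089738071972008	-96.588640298769405	-8228851.449488912	-4902390.522491262
-48.165381995560992	5.789731549583479	467101.195577994	-5879378.688222331
4.543764428763708	57.445031906222766	5387421.623218155	597915.439790808
-12.159477319540059	137.227024565828458	12770219.159238053	-1593837.622545683
28.719789203176788	-52.178034748126080	-4654385.116645778	3685446.158027901
-85.740075103442038	-65.275572082051738	-3359478.511980918	-8411971.469535204
-9.204465329185140	-67.079973037029106	-6266530.851338173	-1208844.031676817
-23.728179000699114	-137.574127971217706	-12477088.071612740	-3070295.154386967
-53.610022422606491	58.746011276615206	4553477.127086850	-6415771.512570436
16.696393297065299	115.075649317395744	10622991.579956200	2179693.723106382
-11.384884552686557	-9.718250089324044	-905381.219768056	-1493143.281994587
-35.201495340853633	20.987062901477060	1822542.001448424	-4457071.615580386
-51.142762662425355	165.052840930422633	13037312.754902313	-6177827.200696123
65.933834065823589	71.609461794895907	4945076.993959032	7455844.488600740
52.353367531772136	88.212559193154675	6904629.488050886	6295678.595460229
18.780903096556301	140.219408629630209	12885007.754054846	2446198.000264718
-27.262298154556582	-102.315392609717193	-9174301.157828188	-3507528.116508720
78.640283212418126	54.059780995448619	3155994.540347673	8196934.760651388
11.154417912448011	78.262021917501670	7293440.368231865	1463150.942146833
-11.833757826888444	123.202054700469262	11470554.885784939	-1551516.142539642
70.479129424743093	-56.237203439318023	-3682062.067364678	7765653.110158130
-31.795842513272220	67.966094056697159	5990625.944272451	-4055846.763332096
34.495097143545877	37.584218088938087	3274403.903702693	4374666.284742764
-32.767622401822862	-32.630027823840493	-2864390.769323979	-4171327.281626978
-41.966663849123201	-143.393127450421218	-12025703.651527913	-5222169.294732584
35.347996552150562	-52.902563838069440	-4591006.837852571	4474106.224544841
-47.891011712305044	166.854509323372383	13486513.753071165	-5851284.077033116
-1.212583154660990	-102.051539419392526	-9581947.447828654	-159657.738249849
14.085007731617878	-139.090322308256788	-12903565.022904512	1843358.323892481
-54.752479803215316	-47.635407094677191	-3658545.136362377	-6522907.565211796
40.698355871086250	-143.646914841846439	-12132863.390580501	5082267.142350391
8.533019373934920	-83.808384538942292	-7834966.832248847	1121070.859459165
21.384573694165027	149.204203957052869	13621736.012757214	2776246.274659045
-22.502600243757939	-65.238450679591381	-5937767.141294695	-2916903.605372435
-14.045986253968451	30.920225236857277	2868697.333126828	-1838313.718325633
-0.909976686598100	-94.051879360217441	-8831177.878474273	-119816.665095582
-5.285119416514107	60.472772783461750	5668864.025101500	-695315.633760731
30.912503221533655	-134.043700440642283	-11857104.368321715	3950219.937652901
13.583240791331065	104.331377979181752	9687191.989801949	1778451.827013913
-14.736366833325931	-27.739423882226589	-2570450.201098834	-1927486.382454831
-87.682785765199853	-113.882260647084735	-5630703.564195192	-8439227.429239012
51.749466696488753	92.969843633456776	7310402.865070755	6237150.005489792
3.411622921403065	19.541714049803801	1833701.996482311	449060.179375014
-30.528139169216480	-22.267796280851115	-1972738.808218506	-3904068.845744899
-0.007916055629863	-93.374624947041639	-8768026.392855713	-1042.333705086
-71.553515704947216	101.291721550098373	6542352.914103598	-7832097.057769777
71.227916769390106	-48.497379586754192	-3145483.408446782	7812248.476941868
86.193565494872615	-164.487351371545543	-8388718.413736435	8419668.464096278
-77.662601717257402	167.532937144084769	9930685.823386310	-8154747.774170889
-24.951305527916873	-169.032669075037774	-15272835.283332409	-3222503.120695565
40.491365696158709	-136.631132055405317	-11553380.095256807	5059271.940144399
-32.694088905652649	-12.307488841663428	-1080736.819785792	-4162615.983832205
11.800757472143005	-105.172221034103856	-9792379.868482715	1547226.617653154
-14.683510632554743	-59.351386469005647	-5500271.795679077	-1920665.175000247
48.261339743034000	24.323487096002651	1961073.712402474	5889181.451565170
80.689734569669952	164.823102813223159	9305607.633969257	8276062.037357276
68.357595031735087	157.072400732824121	10551780.502318660	7626660.423395425
21.284641875208706	-153.397448695715326	-14008288.788699219	2763641.500348540
-59.791720970419718	127.192916253599776	9348196.445094096	-6970716.954690458
78.682926662852651	-119.583484152391733	-6976539.073248649	8198710.987341024
-83.840692553767411	112.115834101164069	5985601.864305856	-8371343.750800253
-35.603135669928385	-73.315001574648264	-6354881.983109522	-4503726.718152619
-38.436025214295142	78.420368621843352	6703663.846409444	-4828539.616289866
30.241372783196027	78.765553809909647	6985783.976843560	3869562.707160192
-2.224100371237981	126.198453512287813	11846678.898082815	-292810.542745294
-71.651615418689289	172.665305586537670	11138245.097160697	-7838027.655025867
-85.737011756892258	-80.826892969319374	-4160098.263862344	-8411916.784617651
18.359571432160266	46.191045122780793	4248694.600219683	2392484.421212580
-1.498933507997009	86.133886429332279	8087006.664417739	-197356.080220292
17.843253355910605	-151.333438472781580	-13935905.343337571	2326553.029106297
11.268200040334065	58.666081596785602	5466391.097044110	1477960.071307810
68.720803060743691	-64.254414489030736	-4297982.392458169	7651170.718022703
73.637846985225025	-121.871144642057686	-7657304.149251032	7953050.910408260
-54.866739645983756	17.809760820513276	1366567.773914713	-6533513.123202620
77.813273026814016	-13.721905052075641	-811496.130724435	8161430.368566980
50.639886232809914	27.748739865566193	2199952.560547297	6128265.375927025
24.468620391242084	51.090332545208469	4623176.719963955	3162544.593264494
28.090879078407085	-0.479209914539382	-42844.032446179	3608856.049145946
8.106600462513086	145.854254678089035	13641325.968728207	1065279.473087955
73.438340737139953	-115.950888579238409	-7305120.065563116	7941940.571712559
-46.945675708775582	-76.035006356606843	-6184667.840332945	-5753747.314279056
17.479614639446240	-51.760209175169393	-4770252.009801285	2280048.136431728
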