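id	class	x1	y1	z1	x2	y2	z2	x3	y3	z3	x4	y4	z4
H	helix	2.07767095911038	0.128361731606292	-2.25	-0.621719849523557	2.39341956353437	-0.75	-2.38362206869721	-0.658284598042746	0.75	0.927670959110382	-1.86349669709792	2.25
E	sheet	-0.25	0	-5.1	0.25	0	-1.7	-0.25	0	1.7	0.25	0	5.1
P	loop	0.975	3.14202605179377e-17	-4.65	-0.975	-1.12583302491977	-1.55	-0.975000000000001	1.12583302491977	1.55	0.975	3.4982842829625e-16	4.65
G	helix	1.425	-5.01920077747749e-17	-3	-1.425	1.64544826719043	-1	-1.425	-1.64544826719043	1	1.425	-5.15557791450769e-16	3
L	loop	2.07767095911038	-0.128361731606292	-2.25	-0.621719849523557	-2.39341956353437	-0.75	-2.38362206869721	0.658284598042746	0.75	0.927670959110382	1.86349669709792	2.25
T-60	loop	-0.25	-2.20836477965032	-3.825	0.25	-2.20836477965032	-0.425	-0.25	0.736121593216773	1.275	0.25	3.68060796608386	2.975
T-30	loop	-0.25	-1.275	-4.75836477965032	0.25	-1.275	-1.35836477965032	-0.25	0.425	1.58612159321677	0.25	2.125	4.53060796608386
T+30	loop	-0.25	1.275	-4.75836477965032	0.25	1.275	-1.35836477965032	-0.25	-0.425	1.58612159321677	0.25	-2.125	4.53060796608386
T+60	loop	-0.25	2.20836477965032	-3.825	0.25	2.20836477965032	-0.425	-0.25	-0.736121593216773	1.275	0.25	-3.68060796608386	2.975
X-60	loop	2.07767095911038	-1.75949440042738	-3.26986273806277	-0.621719849523557	0.505563431500702	-1.76986273806277	-2.38362206869721	0.278749456388801	1.6229905906977	0.927670959110382	0.975181512537874	3.41673488542785
X-45	loop	2.07767095911038	-1.20229473736524	-3.21248889425055	-0.621719849523557	1.06276309456284	-1.71248889425055	-2.38362206869721	-0.0344574404837223	1.50605198435565	0.927670959110382	0.173989083286115	3.41892580414546
X-30	loop	2.07767095911038	-0.678930635883285	-3.01285613203367	-0.621719849523557	1.58612719604479	-1.51285613203367	-2.38362206869721	-0.306726132715681	1.31203405443155	0.927670959110382	-0.600470427445826	3.21367820963579
X-15	helix	2.07767095911038	-0.22506849459745	-2.68456909424846	-0.621719849523557	2.03998933733063	-1.18456909424846	-2.38362206869721	-0.519501958876755	1.05415880221992	0.927670959110382	-1.29541888385642	2.81497938627699
X+15	helix	2.07767095911038	0.357274356883221	-1.73876401490195	-0.621719849523557	2.6223321888113	-0.238764014901947	-2.38362206869721	-0.713616242703646	0.420285567496878	0.927670959110382	-2.26599030299088	1.55724246230702
X+30	loop	2.07767095911038	0.446069364116715	-1.18570102648132	-0.621719849523557	2.71112719604479	0.314298973518682	-2.38362206869721	-0.681726132715681	0.0874849984067818	0.927670959110382	-2.47547042744583	0.783917054555855
X+45	loop	2.07767095911038	0.388695520304496	-0.628501363419177	-0.621719849523557	2.65375335223257	0.871498636580823	-2.38362206869721	-0.564787526373633	-0.225721898465742	0.927670959110382	-2.47766134616344	-0.0172753746959043
X+60	loop	2.07767095911038	0.189062758087611	-0.105137261937227	-0.621719849523557	2.45412059001569	1.39486273806277	-2.38362206869721	-0.370769596449528	-0.497990590697701	0.927670959110382	-2.27241375165377	-0.791734885427845
Y-60	loop	3.02538561205041	0.128361731606292	-1.64148992996964	0.325994803416472	2.39341956353437	-0.141489929969637	-1.85399441184701	-0.658284598042746	-0.917342010758195	-1.49738600361987	-1.86349669709792	2.70032187069747
Y-45	loop	2.85760530017836	0.128361731606292	-1.88292806396683	0.158214491544418	2.39341956353437	-0.382928063966829	-2.14829868720072	-0.658284598042746	-0.568120899152322	-0.867521104522057	-1.86349669709792	2.83397702708598
Y-30	loop	2.63305317650582	0.128361731606292	-2.07271465294003	-0.0663376321281217	2.39341956353437	-0.57271465294003	-2.34218971291668	-0.658284598042746	-0.154627656850197	-0.224525831461016	-1.86349669709792	2.80005696273026
Y-15	helix	2.36703209717115	0.128361731606292	-2.19791605448788	-0.332358711462793	2.39341956353437	-0.697916054487883	-2.42245413601242	-0.658284598042746	0.294958835015183	0.387780750304071	-1.86349669709792	2.60087327396058
Y+15	helix	1.78468924569047	0.128361731606292	-2.22541705466252	-0.914701562943464	2.39341956353437	-0.725417054662521	-2.22833985218553	-0.658284598042746	1.17948553470162	1.35835216943852	-1.86349669709792	1.77134857462342
Y+30	loop	1.50805317650582	0.128361731606292	-2.12584250557496	-1.19133763212812	2.39341956353437	-0.625842505574957	-1.96718971291668	-0.658284598042746	1.55414670968853	1.65047416853898	-1.86349669709792	1.19753830146139
Y+45	loop	1.26661504250863	0.128361731606292	-1.9580621937029	-1.43277576612531	2.39341956353437	-0.458062193702903	-1.61796860131081	-0.658284598042746	1.84845098504223	1.7841293249275	-1.86349669709792	0.567673402363573
Y+60	loop	1.07682845353542	0.128361731606292	-1.73351007003036	-1.62256235509851	2.39341956353437	-0.233510070030363	-1.20447535900868	-0.658284598042746	2.0423420107582	1.75020926057177	-1.86349669709792	-0.0753218706974685
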