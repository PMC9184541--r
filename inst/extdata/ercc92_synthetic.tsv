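spike_id	subgroup	concentration_mix1	concentration_mix2	length
ERCC-00001	A	0.02000000000	0.080000000000	1332
ERCC-00002	B	0.02000000000	0.020000000000	663
ERCC-00003	C	0.02000000000	0.013400000000	1745
ERCC-00004	D	0.02000000000	0.005000000000	1076
ERCC-00005	A	0.03747634846	0.149905393829	408
ERCC-00006	B	0.03747634846	0.037476348457	1489
ERCC-00007	C	0.03747634846	0.025109153466	821
ERCC-00008	D	0.03747634846	0.009369087114	1902
ERCC-00009	A	0.07022383468	0.280895338737	1234
ERCC-00010	B	0.07022383468	0.070223834684	566
ERCC-00011	C	0.07022383468	0.047049969238	1647
ERCC-00012	D	0.07022383468	0.017555958671	979
ERCC-00013	A	0.13158664493	0.526346579726	310
ERCC-00014	B	0.13158664493	0.131586644932	1392
ERCC-00015	C	0.13158664493	0.088163052104	723
ERCC-00016	D	0.13158664493	0.032896661233	1805
ERCC-00017	A	0.24656934789	0.986277391554	1137
ERCC-00018	B	0.24656934789	0.246569347888	468
ERCC-00019	C	0.24656934789	0.165201463085	1550
ERCC-00020	D	0.24656934789	0.061642336972	881
ERCC-00021	A	0.46202594002	1.848103760067	1963
ERCC-00022	B	0.46202594002	0.462025940017	1294
ERCC-00023	C	0.46202594002	0.309557379811	626
ERCC-00024	D	0.46202594002	0.115506485004	1707
ERCC-00025	A	0.86575225622	3.463009024866	1039
ERCC-00026	B	0.86575225622	0.865752256217	371
ERCC-00027	C	0.86575225622	0.580054011665	1452
ERCC-00028	D	0.86575225622	0.216438064054	784
ERCC-00029	A	1.62226166158	6.489046646317	1865
ERCC-00030	B	1.62226166158	1.622261661579	1197
ERCC-00031	C	1.62226166158	1.086915313258	528
ERCC-00032	D	1.62226166158	0.405565415395	1610
ERCC-00033	A	3.03982216591	12.159288663623	941
ERCC-00034	B	3.03982216591	3.039822165906	273
ERCC-00035	C	3.03982216591	2.036680851157	1355
ERCC-00036	D	3.03982216591	0.759955541476	686
ERCC-00037	A	5.69607173687	22.784286947486	1768
ERCC-00038	B	5.69607173687	5.696071736872	1099
ERCC-00039	C	5.69607173687	3.816368063704	431
ERCC-00040	D	5.69607173687	1.424017934218	1512
ERCC-00041	A	10.67339846241	42.693593849650	844
ERCC-00042	B	10.67339846241	10.673398462413	1925
ERCC-00043	C	10.67339846241	7.151176969816	1257
ERCC-00044	D	10.67339846241	2.668349615603	589
ERCC-00045	A	20.00000000000	80.000000000000	1670
ERCC-00046	B	20.00000000000	20.000000000000	1002
ERCC-00047	C	20.00000000000	13.400000000000	333
ERCC-00048	D	20.00000000000	5.000000000000	1415
ERCC-00049	A	37.47634845721	149.905393828831	746
ERCC-00050	B	37.47634845721	37.476348457208	1828
ERCC-00051	C	37.47634845721	25.109153466329	1160
ERCC-00052	D	37.47634845721	9.369087114302	491
ERCC-00053	A	70.22383468430	280.895338737210	1573
ERCC-00054	B	70.22383468430	70.223834684303	904
ERCC-00055	C	70.22383468430	47.049969238483	1986
ERCC-00056	D	70.22383468430	17.555958671076	1317
ERCC-00057	A	131.58664493151	526.346579726055	649
ERCC-00058	B	131.58664493151	131.586644931514	1730
ERCC-00059	C	131.58664493151	88.163052104114	1062
ERCC-00060	D	131.58664493151	32.896661232878	394
ERCC-00061	A	246.56934788841	986.277391553653	1475
ERCC-00062	B	246.56934788841	246.569347888413	807
ERCC-00063	C	246.56934788841	165.201463085237	1888
ERCC-00064	D	246.56934788841	61.642336972103	1220
ERCC-00065	A	462.02594001663	1848.103760066528	551
ERCC-00066	B	462.02594001663	462.025940016632	1633
ERCC-00067	C	462.02594001663	309.557379811144	964
ERCC-00068	D	462.02594001663	115.506485004158	296
ERCC-00069	A	865.75225621661	3463.009024866447	1378
ERCC-00070	B	865.75225621661	865.752256216612	709
ERCC-00071	C	865.75225621661	580.054011665130	1791
ERCC-00072	D	865.75225621661	216.438064054153	1122
ERCC-00073	A	1622.26166157937	6489.046646317494	454
ERCC-00074	B	1622.26166157937	1622.261661579374	1535
ERCC-00075	C	1622.26166157937	1086.915313258180	867
ERCC-00076	D	1622.26166157937	405.565415394843	1949
ERCC-00077	A	3039.82216590587	12159.288663623462	1280
ERCC-00078	B	3039.82216590587	3039.822165905865	612
ERCC-00079	C	3039.82216590587	2036.680851156930	1693
ERCC-00080	D	3039.82216590587	759.955541476466	1025
ERCC-00081	A	5696.07173687160	22784.286947486391	356
ERCC-00082	B	5696.07173687160	5696.071736871598	1438
ERCC-00083	C	5696.07173687160	3816.368063703971	769
ERCC-00084	D	5696.07173687160	1424.017934217899	1851
ERCC-00085	A	10673.39846241263	42693.593849650526	1183
ERCC-00086	B	10673.39846241263	10673.398462412631	514
ERCC-00087	C	10673.39846241263	7151.176969816463	1596
ERCC-00088	D	10673.39846241263	2668.349615603158	927
ERCC-00089	A	19999.99999999999	79999.999999999956	259
ERCC-00090	B	19999.99999999999	19999.999999999989	1340
ERCC-00091	C	19999.99999999999	13399.999999999993	672
ERCC-00092	D	19999.99999999999	4999.999999999997	1753
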