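-3.7031	-1.4385	1.3847	1.7931	0.615	2.1508	0.5005	-1.3026
1.1519	0.0405	1.0298	0.9509	0.0784	-1.5122	-1.0035	-0.7358
0.2951	1.3884	3.79	1.9492	0.2312	-1.6441	-2.9183	-3.0915
-0.8159	0.5672	4.2624	2.2992	-0.9412	-1.0976	-1.0421	-3.232
0.1598	2.4151	3.2423	2.1765	0.3319	-1.246	-2.895	-4.1845
-1.0122	0.2534	2.003	1.9774	1.3611	-0.2241	-0.7046	-3.6541
-0.5821	-0.2414	0.9477	2.3015	0.4142	-1.5381	-0.4544	-0.8473
-0.0849	1.7616	2.0923	0.4255	0.4923	-0.195	-2.231	-2.2608
0.4933	-0.7092	0.4078	1.7042	0.4503	-0.9564	-0.746	-0.6439
0.5495	-0.148	-0.6275	-1.1756	-0.3213	0.5213	0.9807	0.2209
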