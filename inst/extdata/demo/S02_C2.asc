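0.2571	0.3022	-0.0993	0.7906	-0.6755	-0.858	-0.3087	0.5915
0.0985	1.3948	0.1077	0.3735	-0.1475	-0.6233	-1.0672	-0.1364
0.0751	0.5543	1.2061	0.8532	0.5283	-0.4774	-0.7621	-1.9775
1.5426	3.073	4.406	0.4208	-0.9605	-1.829	-2.7669	-3.886
-0.3962	2.1932	2.9114	2.4559	0.2945	-1.7804	-2.9086	-2.7698
0.1323	1.98	2.1985	1.8079	0.3383	-0.0436	-3.0187	-3.3947
-1.4052	1.1185	2.422	1.737	0.8699	-0.3454	-1.4981	-2.8987
0.0289	1.22	1.5925	0.6091	-0.8185	-0.0661	-0.8609	-1.7049
0.0066	-0.0248	-0.442	0.796	1.3509	-0.3601	-1.0569	-0.2696
-2.2242	-0.5	0.5549	0.3612	1.1865	-0.18	0.6664	0.1353
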