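0.8222	-0.3742	0.18	-0.4069	0.075	-0.9189	-0.7558	1.3787
0.2016	0.9156	1.1348	0.89	0.0114	-0.5234	-1.0514	-1.5786
-0.0053	-0.7981	1.9964	1.8654	-0.0086	-1.2212	-0.8747	-0.9539
-0.8213	0.9347	2.1526	1.3443	0.7502	-1.2977	-0.9129	-2.15
1.0872	0.1097	-1.0721	0.8251	1.1205	-1.4529	-0.7801	0.1625
-0.3662	0.9939	1.4044	2.118	0.9214	-2.2877	-1.5395	-1.2443
0.3019	1.6269	-0.2389	0.093	0.0564	-0.3985	-1.0164	-0.4243
-0.673	0.2274	1.0362	0.5286	-0.0418	-0.8099	0.134	-0.4014
0.0578	1.0368	0.4145	-0.6622	-0.1787	-0.9942	-0.0827	0.4087
-0.5486	-0.4031	0.3283	1.6569	0.9278	-0.583	-0.9417	-0.4367
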