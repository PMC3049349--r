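0.3182	0.3433	0.3069	1.1316	0.3285	-0.8907	-0.6513	-0.8864
-0.6948	0.7289	1.4045	-0.098	-0.4611	-0.1463	-0.2822	-0.4509
-1.4367	0.9591	2.0513	0.2532	0.4304	-0.2379	-0.3441	-1.6753
-0.3799	0.1216	0.9242	1.3084	0.3425	-1.256	-0.6463	-0.4146
0.3189	0.4266	1.4103	2.0954	-0.0368	-2.4162	-1.4725	-0.3256
1.0863	0.8882	1.9542	0.73	-0.3097	-1.3242	-2.3831	-0.6416
0.3238	-1.2351	0.7965	0.5316	1.2559	0.3754	-0.6934	-1.3547
-1.0812	-1.634	0.9068	1.1784	1.1826	0.0165	-0.1518	-0.4172
0.2598	-0.3929	-0.2781	0.6095	-0.5842	-0.4217	0.9244	-0.1168
0.7811	-0.5563	-0.6502	0.107	0.8032	0.4934	-1.031	0.0527
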