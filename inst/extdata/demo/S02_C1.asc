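0.6609	0.5978	-0.3372	0.2006	1.0072	-1.1761	-1.335	0.3817
-2.1316	-1.8448	-0.2928	1.9517	1.1658	0.5445	1.5954	-0.9881
-0.4343	0.083	1.0088	1.1989	-2.302	-0.0587	0.8986	-0.3943
-0.6883	-0.1066	0.5176	0.5548	1.4656	0.5044	-0.2623	-1.9852
0.0638	-0.1714	1.1183	1.5975	-0.0972	-0.0636	-1.1729	-1.2745
-0.2736	1.266	1.1717	0.4557	0.844	-0.5007	-1.3941	-1.569
0.1078	-0.1464	1.3117	0.495	0.6277	-1.4892	-1.3632	0.4566
-0.3073	-0.1646	0.9194	0.8658	0.7998	-1.5179	-0.3139	-0.2812
1.2203	0.2307	0.4374	0.2993	0.4578	-0.3249	-1.997	-0.3236
-1.6387	-1.4462	0.6868	0.2883	0.0642	0.3787	1.5679	0.099
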