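-0.7622	1.247	0.061	1.0623	0.9004	0.0998	-0.3774	-2.2309
0.6979	1.4134	0.264	-0.7234	-0.0827	-0.2017	-0.4811	-0.8864
-1.6398	0.254	2.5251	2.7119	1.7249	-1.7478	-1.8404	-1.988
-1.151	1.0352	1.1956	1.2562	0.6481	-0.437	-0.5701	-1.9771
-1.7364	2.3355	4.2523	1.3992	0.1632	-2.3873	-1.3569	-2.6697
0.4387	1.4942	2.4614	1.7571	-0.0637	-2.3501	-1.9202	-1.8174
-0.8498	-0.1439	0.5816	0.4699	1.4897	0.442	-0.2227	-1.7668
0.9279	0.6551	1.3462	0.9355	-0.9103	-0.0092	-1.5253	-1.4199
1.134	-0.2026	-0.718	-1.2659	0.5264	0.4073	0.4013	-0.2825
0.079	-1.35	-1.8376	0.2276	0.0839	0.7312	1.6419	0.424
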