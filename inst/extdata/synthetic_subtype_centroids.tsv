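feature_id	Basal	Her2	LumA	LumB
GENE01	1.371	1.305	-0.307	0.455
GENE02	-0.565	2.287	-1.781	0.705
GENE03	0.363	-1.389	-0.172	1.035
GENE04	0.633	-0.279	1.215	-0.609
GENE05	0.404	-0.133	1.895	0.505
GENE06	-0.106	0.636	-0.43	-1.717
GENE07	1.512	-0.284	-0.257	-0.784
GENE08	-0.095	-2.656	-1.763	-0.851
GENE09	2.018	-2.44	0.46	-2.414
GENE10	-0.063	1.32	-0.64	0.036
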