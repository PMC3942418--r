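rank	reactor	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	published_mean	published_sd
phylum	full	12	13	13	16	16	14	16	15	14	14	15	14	14.3	1.2
phylum	lab	12	13	14	15	16	14	16	15	16	14	15	14	14.5	1.2
class	full	23	23	26	29	31	28	27	28	23	26	26	27	26.4	2.4
class	lab	21	24	27	23	32	29	29	22	23	24	21	23	24.8	3.4
order	full	51	53	52	64	65	61	57	57	56	50	51	51	55.7	5.1
order	lab	49	60	62	58	66	64	64	53	57	53	47	51	57.0	6.1
family	full	65	78	67	84	92	76	62	73	64	63	68	65	71.4	9.0
family	lab	63	71	73	79	87	70	69	62	78	65	59	64	70.0	7.9
genus	full	219	274	231	278	281	256	249	237	215	201	229	205	239.6	26.8
genus	lab	208	242	251	267	278	245	231	205	261	237	197	223	237.1	24.4
otu	full	3611	3043	2787	3878	3592	3317	2706	2847	3452	3027	2779	2513	3055.8	408.0
otu	lab	2454	2983	3150	3275	3742	2773	2870	2697	3130	2993	2137	2452	2874.8	426.2
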