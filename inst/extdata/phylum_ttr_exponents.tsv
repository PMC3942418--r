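phylum	reactor	relative_abundance	w	r_squared
Proteobacteria	full	25.8	0.33	0.951
Bacteroidetes	full	41.0	0.32	0.965
Acidobacteria	full	11.7	0.37	0.952
Chloroflexi	full	1.9	0.38	0.949
Verrucomicrobia	full	5.6	0.37	0.968
Planctomycetes	full	1.8	0.42	0.967
Firmicutes	full	2.5	0.42	0.975
Actinobacteria	full	0.3	0.41	0.971
Chlamydiae	full	0.6	0.46	0.954
Spirochaetes	full	0.6	0.46	0.969
Synergistetes	full	0.1	0.49	0.972
Fusobacteria	full	0.1	0.47	0.955
TM7	full	0.1	0.52	0.967
Euryarchaeota	full	0.1	0.53	0.981
OP10	full	0.2	0.51	0.977
Proteobacteria	lab	43.1	0.34	0.954
Bacteroidetes	lab	27.1	0.35	0.955
Acidobacteria	lab	4.6	0.36	0.944
Chloroflexi	lab	9.0	0.37	0.983
Verrucomicrobia	lab	8.5	0.38	0.957
Planctomycetes	lab	1.1	0.48	0.962
Firmicutes	lab	3.7	0.46	0.967
Actinobacteria	lab	0.6	0.47	0.971
Chlamydiae	lab	0.3	0.52	0.966
Spirochaetes	lab	0.4	0.54	0.958
Synergistetes	lab	0.1	0.54	0.973
Fusobacteria	lab	0.1	0.55	0.982
TM7	lab	0.1	0.57	0.981
Euryarchaeota	lab	0.0	0.55	0.979
OP10	lab	0.1	0.56	0.978
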