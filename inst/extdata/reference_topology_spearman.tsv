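network	centralization_degree	cluster_count	connectance	edge_count	giant_component_size	hub_count	ks_stat	mean_degree	modularity	node_count
V1-Bst-79X	0.11	4.00	0.23	27.00	6.00	6.00	0.44	3.38	0.62	16.00
V6-Bst-79X	0.06	4.00	0.22	37.00	6.00	6.00	0.23	3.89	0.71	19.00
R2-Bst-79X	0.05	7.00	0.13	55.00	6.00	12.00	0.28	3.67	0.80	30.00
R6-Bst-79X	0.04	7.00	0.10	24.00	4.00	4.00	0.36	2.18	0.84	22.00
V1-Ctrl-79X	0.00	2.00	0.40	6.00	3.00	6.00	NA	2.00	0.50	6.00
V6-Ctrl-79X	0.00	2.00	0.40	6.00	3.00	6.00	NA	2.00	0.50	6.00
R2-Ctrl-79X	0.06	6.00	0.13	31.00	5.00	5.00	0.36	2.82	0.79	22.00
R6-Ctrl-79X	0.13	6.00	0.16	36.00	7.00	7.00	0.36	3.27	0.63	22.00
V1-Bst-10X	0.00	2.00	0.40	6.00	3.00	6.00	NA	2.00	0.50	6.00
V6-Bst-10X	0.05	6.00	0.13	34.00	5.00	5.00	0.25	2.96	0.80	23.00
R2-Bst-10X	0.01	4.00	0.20	21.00	4.00	4.00	0.36	2.80	0.73	15.00
R6-Bst-10X	0.08	6.00	0.14	39.00	6.00	6.00	0.33	3.25	0.77	24.00
V1-Ctrl-10X	0.00	3.00	0.25	9.00	3.00	9.00	NA	2.00	0.67	9.00
V6-Ctrl-10X	0.00	1.00	1.00	6.00	4.00	4.00	NA	3.00	0.00	4.00
R2-Ctrl-10X	0.08	6.00	0.16	51.00	7.00	7.00	0.23	3.92	0.72	26.00
R6-Ctrl-10X	0.10	5.00	0.19	43.00	7.00	7.00	0.28	3.91	0.68	22.00
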