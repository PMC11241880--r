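network	centralization_degree	cluster_count	connectance	edge_count	giant_component_size	hub_count	ks_stat	mean_degree	modularity	node_count
V1-Bst-79X	0.16	7.00	0.12	627.00	31.00	29.00	0.21	12.29	0.64	102.00
V6-Bst-79X	0.20	6.00	0.11	489.00	36.00	21.00	0.24	10.19	0.72	96.00
R2-Bst-79X	0.11	8.00	0.06	447.00	27.00	19.00	0.13	7.58	0.81	118.00
R6-Bst-79X	0.16	6.00	0.12	719.00	32.00	31.00	0.17	13.31	0.67	108.00
V1-Ctrl-79X	0.13	5.00	0.17	700.00	30.00	27.00	0.17	15.56	0.61	90.00
V6-Ctrl-79X	0.14	5.00	0.13	485.00	24.00	21.00	0.18	11.02	0.73	88.00
R2-Ctrl-79X	0.10	5.00	0.10	399.00	38.00	19.00	0.19	8.77	0.77	91.00
R6-Ctrl-79X	0.29	5.00	0.14	951.00	61.00	49.00	0.20	16.12	0.35	118.00
V1-Bst-10X	0.14	5.00	0.15	725.00	29.00	29.00	0.20	14.50	0.64	100.00
V6-Bst-10X	0.14	5.00	0.17	1398.00	43.00	40.00	0.14	21.51	0.61	130.00
R2-Bst-10X	0.26	4.00	0.18	1599.00	88.00	61.00	0.25	24.05	0.25	133.00
R6-Bst-10X	0.18	6.00	0.15	1604.00	49.00	48.00	0.18	22.12	0.57	145.00
V1-Ctrl-10X	0.11	5.00	0.12	684.00	29.00	25.00	0.18	12.91	0.74	106.00
V6-Ctrl-10X	0.15	7.00	0.18	448.00	56.00	23.00	0.18	12.62	0.62	71.00
R2-Ctrl-10X	0.16	5.00	0.11	743.00	56.00	31.00	0.18	12.49	0.73	119.00
R6-Ctrl-10X	0.16	4.00	0.11	646.00	53.00	30.00	0.17	12.07	0.68	107.00
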