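# Published per-subject symmetry ratios (r) for the 6 h awake and asleep
# segments of the same cohorts. NA = no continuous 6 h period available.
subject	condition	awake	asleep
nsr01	healthy	1.88	3.17
nsr02	healthy	1.52	2.90
nsr03	healthy	1.19	3.01
nsr04	healthy	1.58	4.09
nsr05	healthy	0.72	2.99
nsr06	healthy	0.92	3.09
nsr07	healthy	1.34	20.70
nsr08	healthy	2.28	3.36
nsr09	healthy	1.41	3.99
nsr10	healthy	1.04	3.06
nsr11	healthy	0.95	3.10
nsr12	healthy	3.05	3.19
nsr13	healthy	1.61	2.46
nsr14	healthy	1.47	2.86
nsr15	healthy	0.95	31.86
nsr16	healthy	0.83	1.65
nsr17	healthy	1.03	1.57
nsr18	healthy	2.15	1.45
nsr19	healthy	2.06	2.32
nsr20	healthy	1.32	1.45
nsr21	healthy	1.01	2.38
nsr22	healthy	3.10	3.67
nsr23	healthy	1.14	1.74
nsr24	healthy	4.15	1.55
nsr25	healthy	0.79	1.85
nsr26	healthy	0.75	8.41
nsr27	healthy	2.41	2.80
nsr28	healthy	2.30	3.50
nsr29	healthy	1.05	2.92
nsr30	healthy	2.53	17.01
nsr31	healthy	1.82	2.73
nsr32	healthy	1.18	3.40
nsr33	healthy	3.59	6.52
nsr34	healthy	1.93	9.43
nsr35	healthy	1.94	1.49
nsr36	healthy	3.52	4.53
nsr37	healthy	3.80	3.16
nsr38	healthy	1.98	2.40
nsr39	healthy	2.81	3.48
nsr40	healthy	2.57	5.39
nsr41	healthy	1.69	1.22
nsr42	healthy	2.12	1.40
nsr43	healthy	3.22	3.07
nsr44	healthy	2.14	2.45
nsr45	healthy	2.17	4.09
nsr46	healthy	1.05	3.73
nsr47	healthy	1.85	2.87
nsr48	healthy	0.86	2.91
nsr49	healthy	1.14	14.96
nsr50	healthy	1.25	2.76
nsr51	healthy	1.52	3.88
nsr52	healthy	1.28	3.09
nsr53	healthy	2.52	2.91
nsr54	healthy	0.86	3.86
chf001	chf	1.45	1.56
chf002	chf	1.06	0.62
chf004	chf	1.44	1.16
chf005	chf	0.63	1.43
chf006	chf	NA	1.85
chf007	chf	2.91	1.06
chf008	chf	3.67	1.94
chf010	chf	1.04	0.28
chf011	chf	1.70	1.51
chf012	chf	1.02	1.20
chf013	chf	0.30	1.02
chf014	chf	0.89	1.01
chf015	chf	0.62	1.05
chf201	chf	2.70	1.15
chf202	chf	0.80	0.70
chf203	chf	2.84	3.71
chf204	chf	2.13	1.60
chf205	chf	0.61	0.47
chf207	chf	0.75	1.28
chf208	chf	2.56	1.62
chf209	chf	NA	0.80
chf210	chf	2.45	2.01
chf211	chf	0.82	2.51
chf212	chf	0.44	0.66
chf213	chf	0.89	2.65
chf214	chf	0.98	1.51
chf215	chf	2.45	0.75
chf216	chf	2.48	1.89
chf217	chf	1.30	3.63
chf218	chf	0.82	3.28
chf219	chf	1.10	2.20
chf220	chf	0.91	1.25
chf221	chf	0.82	2.18
chf223	chf	0.64	1.09
chf224	chf	1.56	2.60
chf225	chf	0.68	0.98
chf226	chf	2.45	3.17
chf227	chf	1.20	2.56
chf228	chf	1.12	3.01
chf229	chf	0.53	0.69
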