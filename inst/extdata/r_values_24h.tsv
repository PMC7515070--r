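# Published per-subject symmetry ratios (r) for 24 h RR recordings:
# PhysioNet Normal Sinus Rhythm RR cohort (healthy) and the two CHF RR
# cohorts (condition chf, with NYHA class). Inputs for replicating the
# published group aggregates.
subject	condition	nyha	r
nsr01	healthy	none	1.85
nsr02	healthy	none	1.52
nsr03	healthy	none	1.14
nsr04	healthy	none	2.05
nsr05	healthy	none	1.80
nsr06	healthy	none	2.66
nsr07	healthy	none	2.12
nsr08	healthy	none	1.76
nsr09	healthy	none	1.22
nsr10	healthy	none	1.71
nsr11	healthy	none	1.04
nsr12	healthy	none	2.94
nsr13	healthy	none	1.34
nsr14	healthy	none	1.40
nsr15	healthy	none	1.34
nsr16	healthy	none	1.24
nsr17	healthy	none	1.40
nsr18	healthy	none	1.27
nsr19	healthy	none	1.69
nsr20	healthy	none	1.14
nsr21	healthy	none	2.19
nsr22	healthy	none	3.38
nsr23	healthy	none	1.97
nsr24	healthy	none	2.07
nsr25	healthy	none	0.92
nsr26	healthy	none	0.83
nsr27	healthy	none	4.47
nsr28	healthy	none	2.20
nsr29	healthy	none	1.44
nsr30	healthy	none	6.65
nsr31	healthy	none	2.35
nsr32	healthy	none	1.81
nsr33	healthy	none	3.93
nsr34	healthy	none	2.75
nsr35	healthy	none	1.18
nsr36	healthy	none	1.24
nsr37	healthy	none	2.56
nsr38	healthy	none	1.23
nsr39	healthy	none	1.49
nsr40	healthy	none	3.34
nsr41	healthy	none	1.28
nsr42	healthy	none	2.21
nsr43	healthy	none	1.87
nsr44	healthy	none	1.57
nsr45	healthy	none	1.76
nsr46	healthy	none	1.82
nsr47	healthy	none	1.01
nsr48	healthy	none	0.88
nsr49	healthy	none	1.06
nsr50	healthy	none	0.83
nsr51	healthy	none	1.15
nsr52	healthy	none	1.05
nsr53	healthy	none	1.69
nsr54	healthy	none	0.94
chf001	chf	III-IV	1.09
chf002	chf	III-IV	1.05
chf003	chf	III-IV	1.73
chf004	chf	III-IV	1.18
chf005	chf	III-IV	0.72
chf006	chf	III-IV	1.89
chf007	chf	III-IV	2.41
chf008	chf	III-IV	2.51
chf009	chf	III-IV	0.87
chf010	chf	III-IV	1.03
chf011	chf	III-IV	1.54
chf012	chf	III-IV	0.89
chf013	chf	III-IV	0.71
chf014	chf	III-IV	1.01
chf015	chf	III-IV	0.60
chf201	chf	III	1.51
chf202	chf	III	0.85
chf203	chf	III	1.25
chf204	chf	III	1.62
chf205	chf	III	0.47
chf206	chf	III	0.91
chf207	chf	III	0.82
chf208	chf	III	0.77
chf209	chf	III	0.88
chf210	chf	III	2.02
chf211	chf	II	1.48
chf212	chf	II	0.41
chf213	chf	I	1.34
chf214	chf	II	0.89
chf215	chf	II	0.86
chf216	chf	II	0.94
chf217	chf	I	1.99
chf218	chf	I	1.04
chf219	chf	III	1.39
chf220	chf	II	1.02
chf221	chf	I	1.11
chf222	chf	III	0.76
chf223	chf	III	0.87
chf224	chf	II	1.85
chf225	chf	III	0.78
chf226	chf	II	2.44
chf227	chf	III	1.27
chf228	chf	III	1.25
chf229	chf	III	0.54
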