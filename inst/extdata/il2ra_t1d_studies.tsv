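study_id	year	country	ancestry	snp	design	case_counts	control_counts	reported_or	ci_low	ci_high	orientation	n_cases	n_controls	maf_cases	maf_controls
Lowe_set1	2007	UK	European	rs11594656	case_control	1744/994/136	1385/956/143	0.84	0.76	0.92	minor	2965	2548	0.213	0.244
Lowe_set2	2007	UK	European	rs11594656	case_control	3186/1827/246	3850/2548/411	0.87	0.81	0.92	minor	5259	6809	0.220	0.247
Lowe_set1	2007	UK	European	rs41295061	case_control	2543/344/20	2002/457/35	0.61	0.53	0.70	minor	2965	2548	0.065	0.103
Lowe_set2	2007	UK	European	rs41295061	case_control	4609/675/28	5520/1250/85	0.65	0.59	0.71	minor	5312	6855	0.069	0.104
Kawasaki	2009	Japan	Asian	rs11594656	case_control	836/43/2	570/35/1	0.91	0.59	1.41	minor	882	606	0.027	0.031
Kawasaki	2009	Japan	Asian	rs3118470	case_control	206/427/239	159/298/135	1.18	1.01	1.35	minor	872	592	0.519	0.479
Kawasaki	2009	Japan	Asian	rs706778	case_control	307/421/149	170/309/123	1.23	1.06	1.43	major	877	602	0.410	0.461
Maier	2009	UK/US	European	rs2104286	case_control	ND	ND	0.80	0.76	0.85	minor	6425	6862	ND	ND
Grant_set1	2009	UK	European	rs3118470	case_control	ND	ND	1.21	1.11	1.31	minor	2000	3000	0.361	0.319
Grant_set2	2009	US	European	rs3118470	case_control	ND	ND	1.30	1.12	1.52	minor	563	1146	0.365	0.306
Aminkeng	2010	Belgium	European	rs41295061	case_control	ND	ND	0.63	0.52	0.75	minor	1954	2082	0.054	0.084
Klinker	2010	Finland	European	rs11594656	case_control	ND	ND	0.98	0.82	1.17	minor	591	1538	ND	ND
Klinker	2010	Finland	European	rs41295061	case_control	ND	ND	0.95	0.74	1.25	minor	591	1538	ND	ND
Yamashita	2011	Japan	Asian	rs706778	case_control	ND	ND	1.2	1.0	1.4	minor	790	953	ND	ND
Espino-Paisan	2011	Spain	European	rs11594656	case_control	205/179/46	375/330/86	0.99	0.82	1.19	minor	430	791	0.315	0.317
Espino-Paisan	2011	Spain	European	rs2104286	case_control	277/135/18	488/268/42	0.88	0.71	1.08	minor	430	798	0.199	0.221
Espino-Paisan	2011	Spain	European	rs41295061	case_control	393/35/3	704/105/2	0.69	0.47	1.02	minor	431	811	0.048	0.067
Kisand	2012	Estonia	European	rs706778	case_control	ND	ND	1.08	0.81	1.44	minor	229	154	0.47	0.45
Fichna	2012	Poland	European	rs11594656	case_control	273/155/17	373/248/50	0.77	0.63	0.94	minor	445	671	0.212	0.259
Fichna	2012	Poland	European	rs2104286	case_control	312/123/10	457/187/27	0.89	0.72	1.09	minor	445	671	0.161	0.180
Fichna	2012	Poland	European	rs3118470	case_control	153/217/75	283/306/72	1.30	1.09	1.55	minor	445	671	0.412	0.335
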