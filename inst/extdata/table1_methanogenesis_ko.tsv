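ko	pathway_group	enzyme	BP06	BP07	BP08	BP12	BP15	BP10	BP13	BP01	BP16	BP05	BP02	BP03	BP04	BP14	BP09	BP11
K00925	acetoclastic	Acetate kinase (ackA)	0.218	0.233	0.228	0.268	0.149	0.204	0.215	0.063	0.12	0.148	0.492	0.515	0.145	0.349	0.309	0.269
K00625	acetoclastic	Phosphate acetyltransferase (pta)	0.097	0.083	0.077	0.106	0.078	0.04	0.054	0.015	0.031	0.189	0.632	0.63	0.09	0.448	0.546	0.244
K01895	acetoclastic	Acetyl-coenzyme A synthetase (ACSS)	0.116	0.071	0.062	0.077	0.105	0.118	0.092	5.218	0.043	4.268	0.155	0.061	0.056	0.977	0.056	0.066
K00193	acetoclastic	Acetyl-CoA decarbonylase/synthase beta (cdh)	0.434	0.31	0.255	0.705	0.201	0.275	0.314	1.622	0.099	2.574	3.578	3.325	0.165	3.146	1.783	1.961
K00197	acetoclastic	Acetyl-CoA decarbonylase/synthase gamma (cdh)	0.824	0.861	0.788	0.829	1.219	0.437	0.951	1.673	0.229	2.344	3.862	3.516	0.537	2.89	2.049	1.69
K00194	acetoclastic	Acetyl-CoA decarbonylase/synthase delta (cdh)	0.414	0.475	0.434	0.409	0.528	0.223	0.44	0.794	0.1	0.889	1.091	1.083	0.332	0.892	0.491	0.526
K00577	shared	Tetrahydromethanopterin S-methyltransferase A (mtr)	0.521	0.486	0.483	0.566	0.239	0.405	0.451	0.624	0.237	0.576	0.61	0.718	0.35	0.528	0.5	0.53
K00578	shared	Tetrahydromethanopterin S-methyltransferase B (mtr)	0.002	0.003	0.003	0.004	0.007	0.004	0.002	0.003	0.001	0.006	0.021	0.019	0	0.014	0.011	0.013
K00579	shared	Tetrahydromethanopterin S-methyltransferase C (mtr)	0	0	0.001	0	0	0.001	0	0.004	0.004	0.002	0.003	0.001	0.007	0	0	0
K00580	shared	Tetrahydromethanopterin S-methyltransferase D (mtr)	0.063	0.053	0.046	0.084	0.024	0.052	0.067	0.04	0.032	0.023	0.005	0.013	0.068	0.016	0.018	0.027
K00581	shared	Tetrahydromethanopterin S-methyltransferase E (mtr)	0.26	0.196	0.204	0.344	0.122	0.22	0.275	0.15	0.097	0.146	0.176	0.171	0.185	0.142	0.149	0.188
K00582	shared	Tetrahydromethanopterin S-methyltransferase F (mtr)	0	0	0	0	0	0	0	0	0	0	0.001	0	0	0.001	0	0
K00583	shared	Tetrahydromethanopterin S-methyltransferase G (mtr)	0	0	0	0	0.002	0	0.001	0	0	0.004	0.008	0.005	0	0.007	0.008	0.007
K00584	shared	Tetrahydromethanopterin S-methyltransferase H (mtr)	0.246	0.245	0.26	0.394	0.229	0.222	0.233	0.633	0.199	0.713	1.209	1.47	0.299	1.086	1.002	0.841
K00200	hydrogenotrophic	Formylmethanofuran dehydrogenase A (fmd)	0.184	0.092	0.069	0.174	0.075	0.089	0.114	0.047	0.284	0.027	0.035	0.033	0.371	0.04	0.056	0.131
K00201	hydrogenotrophic	Formylmethanofuran dehydrogenase B (fmd)	0.289	0.308	0.28	0.338	0.077	0.25	0.25	0.095	0.444	0.107	0.137	0.15	0.444	0.142	0.166	0.246
K00202	hydrogenotrophic	Formylmethanofuran dehydrogenase C (fmd)	0.061	0.085	0.075	0.085	0.014	0.071	0.079	0.042	0.157	0.022	0.022	0.03	0.104	0.025	0.027	0.059
K00203	hydrogenotrophic	Formylmethanofuran dehydrogenase D (fmd)	0.053	0.062	0.06	0.073	0.035	0.065	0.056	0.002	0.077	0.003	0.01	0.008	0.071	0.021	0.022	0.047
K11261	hydrogenotrophic	Formylmethanofuran dehydrogenase E (fmd)	0.485	0.34	0.293	0.281	0.09	0.324	0.439	0.026	0.14	0.057	0.131	0.089	0.135	0.132	0.297	0.27
K00205	hydrogenotrophic	Uncharacterized protein	0.074	0.067	0.06	0.097	0.021	0.051	0.069	0.009	0.092	0.033	0.003	0.007	0.17	0.02	0.046	0.066
K00672	hydrogenotrophic	Formylmethanofuran-tetrahydromethanopterin N-formyltransferase (ftr)	0.129	0.169	0.159	0.136	0.03	0.108	0.096	0.048	0.318	0.035	0.021	0.023	0.132	0.034	0.05	0.07
K01499	hydrogenotrophic	Methenyltetrahydromethanopterin cyclohydrolase (mch)	0.047	0.067	0.05	0.081	0.015	0.052	0.032	0.004	0.074	0.011	0.02	0.022	0.145	0.026	0.021	0.054
K00319	hydrogenotrophic	Methylenetetrahydromethanopterin dehydrogenase (mtd)	3.147	3.45	3.783	3.019	0.911	2.968	3.261	0.716	4.184	0.78	0.225	0.461	3.794	0.811	1.296	1.427
K13942	hydrogenotrophic	5,10-methenyltetrahydromethanopterin hydrogenase (hmd)	0	0	0	0	0.005	0	0	0.002	0	0	0.001	0.001	0.007	0	0	0
K00320	hydrogenotrophic	5,10-methylenetetrahydromethanopterin reductase (mer)	5.384	5.908	6.07	7.065	2.679	5.034	5.372	1.773	7.457	1.525	0.658	1.008	7.922	1.389	2.424	3.152
K00399	common	Methyl-CoM reductase alpha (mcr)	8.01	6.397	6.47	4.849	3.222	4.739	6.355	6.625	3.292	8.172	12.755	13.288	4.747	11.437	8.533	9.775
K00401	common	Methyl-CoM reductase beta (mcr)	8.002	6.508	6.344	4.731	1.755	4.384	5.717	5.649	4.351	4.78	6.689	6.593	6.703	5.882	5.438	5.988
K00402	common	Methyl-CoM reductase gamma (mcr)	6.186	5.383	5.367	4.618	2.532	3.885	4.731	7.039	2.708	7.129	13.444	13.935	4.923	11.247	9.987	10.42
K03388	common	Heterodisulfide reductase A2 (hdr)	0.604	0.546	0.543	0.594	0.602	0.647	0.577	0.079	0.573	0.109	0.051	0.074	0.917	0.215	0.208	0.361
K03389	common	Heterodisulfide reductase B2 (hdr)	0.05	0.047	0.042	0.072	0.027	0.05	0.047	0.009	0.075	0.007	0.005	0.011	0.146	0.015	0.013	0.04
K03390	common	Heterodisulfide reductase C2 (hdr)	0.03	0.024	0.024	0.042	0.021	0.035	0.032	0.006	0.045	0.005	0.003	0.007	0.074	0.006	0.007	0.028
K08264	common	Heterodisulfide reductase D (hdr)	0.003	0.002	0.002	0.032	0.022	0.001	0.018	0.213	0.001	0.18	0.157	0.232	0.004	0.142	0.123	0.096
K08265	common	Heterodisulfide reductase E (hdr)	0	0	0	0	0	0	0	0	0	0	0.002	0.002	0	0.002	0.001	0.002
K14126	common	F420-non-reducing hydrogenase large subunit (mvh)	0.035	0.037	0.044	0.022	0.025	0.021	0.018	0.004	0.028	0.035	0.009	0.015	0.048	0.023	0.025	0.018
K14127	common	F420-non-reducing hydrogenase iron-sulfur subunit (mvh)	0	0	0	0.001	0	0	0	0.002	0	0.011	0.003	0.006	0.005	0.002	0	0.001
K22516	common	Formate dehydrogenase alpha (fdh)	0.392	0.66	0.663	0.665	0.355	0.474	0.538	0.558	2.457	0.431	0.153	0.301	1.524	0.263	0.248	0.425
K00125	common	Formate dehydrogenase beta (fdh)	0.11	0.147	0.14	0.152	0.136	0.095	0.098	0.099	0.653	0.067	0.045	0.08	0.48	0.057	0.045	0.095
K14080	methylotrophic	Methylcobalamin:coenzyme M methyltransferase (MtaA)	0	0	0	0	0.001	0	0.001	0	0	0.006	0.019	0.022	0	0.016	0.021	0.016
K04480	methylotrophic	Methanol-corrinoid protein Co-methyltransferase (MtaB)	0.019	0.176	0.172	0.116	0.104	0.023	0.067	0.326	0.042	0.609	1.167	0.512	0.079	1.44	1.019	0.498
K14081	methylotrophic	Methanol-corrinoid protein (MtaC)	0.015	0.026	0.024	0.031	0.024	0.007	0.014	0.045	0.007	0.146	0.298	0.124	0.006	0.361	0.249	0.139
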