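metabolite	kegg	vip_mean	log2_fc	p_value	fdr_printed	cv_percent	validation_level
Caffeine *	C07481	1.84	-1.97	4.3e-3	0.033	24.4	2
Citrulline	C00327	1.83	0.55	5.4e-3	0.033	14.2	1
1-Methyladenosine	C02494	1.80	0.40	1.9e-3	0.033	11.5	2
3-Methoxytyramine *	C05587	1.79	-1.16	0.012	0.049	26.7	1
4-Acetamidobutanoate	C02946	1.69	0.43	6.1e-3	0.033	9.2	2
N-Acetylserotonin	C00978	1.65	0.59	6.2e-3	0.033	16.8	1
O-Succinyl-homoserine	C01118	1.64	0.28	4.7e-3	0.033	14.3	1
N6- (delta2-isopentenyl)-adenine [M + H]	C04083	1.64	0.36	9.8e-3	0.045	5.4	1
Trigonelline	C01004	1.59	0.20	0.021	0.067	11.3	1
5-Hydroxytryptophan	C00643	1.47	0.57	0.016	0.057	15.8	1
Kynurenate	C01717	1.37	0.60	0.039	0.113	9.1	1
N-Acetylneuraminate	C00270	1.37	-0.27	0.062	0.117	7.0	2
N6- (delta2-isopentenyl)-adenine [M - H]	C04083	1.32	0.29	0.075	0.126	8.3	1
N-Acetylphenylalanine * [M + H]	C03519	1.32	0.23	0.054	0.116	6.9	1
Deoxyuridine	C00526	1.31	-0.37	0.050	0.114	13.8	1
Homogentisate	C00544	1.28	0.21	0.050	0.114	18.6	1
5-Hydroxyindoleacetate	C05635	1.26	-0.38	0.101	0.135	11.7	1
Pipecolate	C00408	1.24	0.37	0.042	0.113	7.5	1
N-Acetylleucine	C02710	1.19	0.15	0.145	0.178	5.8	1
Indole-3-acetate	C00954	1.19	0.54	0.066	0.117	12.2	2
Uridine	C00299	1.17	0.19	0.087	0.132	7.4	2
Indoxyl sulfate *	C08481	1.17	-0.35	0.244	0.252	24.0	2
N-Acetyltryptophan *	C03137	1.12	0.35	0.058	0.116	4.3	1
Deoxycarnitine	C01181	1.10	-0.27	0.214	0.228	6.8	1
Xanthosine	C01762	1.09	0.26	0.096	0.134	8.8	1
Phenylacetate	C07086	1.08	0.18	0.202	0.222	8.7	2
Ketoleucine	C00233	1.07	0.07	0.083	0.132	7.6	2
Carnitine	C00318	1.07	-0.18	0.166	0.189	5.8	2
Guanosine	C00387	1.06	0.13	0.162	0.189	7.8	2
N-Acetylphenylalanine * [M - H]	C03519	1.03	0.13	0.260	0.260	9.3	1
4-Pyridoxate	C00847	1.02	0.48	0.094	0.134	12.2	1
4-Hydroxybenzoate	C00156	1.02	0.17	0.113	0.145	11.5	1
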