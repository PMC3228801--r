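virus	chr	strand	start	end	length	or	adj_p	n_genes
hiv	chr11	+	63052973	68240744	5187771	6.73	1.16e-052	177
hiv	chr6	-	29857643	34003291	4145648	25.59	7.53e-046	171
hiv	chr16	-	0	3573133	3573133	9.82	1.85e-045	171
hiv	chr11	-	63408683	68252636	4843953	5.23	6.59e-045	169
hiv	chr6	+	29653216	33939640	4286424	31.23	2.42e-043	179
hiv	chr16	+	0	3106569	3106569	13.06	3.32e-042	153
hiv	chr1	+	0	4770330	4770330	14.32	1.66e-027	89
hiv	chr3	-	46696908	53554160	6857252	4.03	1.58e-025	159
hiv	chr17	-	70567573	74031223	3463650	4.35	1.14e-024	81
hiv	chr17	+	77083925	78700791	1616866	8.53	2.45e-024	56
hiv	chr9	+	136302969	140273252	3970283	7.96	4.03e-023	97
hiv	chr1	-	151528646	154707353	3178707	4.77	4.52e-020	114
hiv	chr9	-	135483396	140273252	4789856	6.70	1.62e-019	105
hiv	chr3	+	46805137	51013082	4207945	3.78	1.18e-014	101
hiv	chr1	+	152393200	155051471	2658271	3.61	1.36e-014	97
hiv	chr8	+	143266499	146274826	3008327	5.29	1.76e-013	94
hiv	chr17	-	76476613	78537508	2060895	4.42	1.85e-013	67
hiv	chr2	-	26376098	28509807	2133709	5.32	4.64e-013	51
hiv	chr8	-	142937251	146274826	3337575	5.58	7.07e-013	94
hiv	chr17	+	71000437	72361727	1361290	5.03	2.53e-012	50
mlv	chr18	+	71458533	76117153	4658620	14.38	1.65e-011	17
mlv	chr21	-	38477753	39470763	993010	23.96	1.13e-010	5
hiv	chr22	+	48573053	49691432	1118379	6.34	8.99e-010	38
hiv	chr20	-	60274607	62435964	2161357	6.34	8.99e-010	60
mlv	chr17	+	51301476	53344785	2043309	15.10	5.64e-009	12
hiv	chr4	-	0	3791201	3791201	4.67	1.23e-008	61
hiv	chr16	+	86724460	88827254	2102794	4.08	3.24e-008	45
mlv	chr20	+	51190248	52356969	1166721	13.94	5.88e-008	6
hiv	chr19	+	54403063	55308772	905709	5.97	7.82e-008	47
mlv	chr12	+	115324321	117477353	2153032	10.89	1.10e-007	16
mlv	chr6	-	5956453	7313927	1357474	33.96	1.20e-007	6
hiv	chr2	+	26617223	28096371	1479148	3.50	1.34e-007	47
hiv	chr19	-	54293977	55393350	1099373	5.65	4.17e-007	54
hiv	chr22	-	48767773	49691432	923659	4.40	4.85e-007	33
hiv	chr2	-	185808293	188459285	2650992	8.25	5.51e-007	7
mlv	chr18	-	71648647	73379689	1731042	10.02	1.04e-006	5
hiv	chr12	+	47052128	48977359	1925231	4.53	1.39e-006	53
hiv	chr15	+	38942654	41945536	3002882	3.80	2.97e-006	61
mlv	chr20	-	51173685	52422011	1248326	9.58	3.17e-006	6
mlv	chr3	+	70940451	72487606	1547155	9.36	5.55e-006	4
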