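# SYNTHETIC stand-in for the 40-value correlated contact potential amino-acid table.
# The canonical values live in the published literature and are not
# redistributed here; these deterministic placeholder values keep the
# feature pipeline runnable. Replace this file with a real table (same
# layout: residue row names, tab-separated numeric columns) via
# loadAminoAcidTables(path = <dir>).
res	v1	v2	v3	v4	v5	v6	v7	v8	v9	v10	v11	v12	v13	v14	v15	v16	v17	v18	v19	v20	v21	v22	v23	v24	v25	v26	v27	v28	v29	v30	v31	v32	v33	v34	v35	v36	v37	v38	v39	v40
A	0.114	-0.117	0.192	-0.382	0.285	-0.097	-0.553	-0.232	0.005	0.378	0.489	-0.621	0.419	-0.02	-0.336	-0.825	-0.4	1.079	-0.295	-1.195	-0.133	0.37	-0.016	0.133	0.142	0.981	0.135	1.085	1.049	-0.154	0.277	0.043	0.625	0.257	-0.179	0.461	0.027	-0.905	-0.78	0.604
R	0.259	1.209	-0.615	0.582	0.424	0.008	0.648	0.025	0.724	0.192	-0.706	-0.358	0.482	0.022	-0.452	-0.661	0.525	0.011	-0.31	0.383	-0.142	0.728	0.224	0.221	-0.819	-1.11	-0.497	0.163	-0.803	0.067	-0.087	0.285	0.617	0.334	0.385	0.149	-0.854	0.512	-0.015	0.754
N	0.294	-0.327	0.463	0.167	-0.236	-0.447	1.192	0.277	0.453	0.379	0.145	0.255	-0.077	-0.146	-0.619	0.411	0.173	0.194	0.424	0.462	-0.781	-0.242	0.027	-0.618	-0.364	-0.061	0.279	-0.128	-0.166	-0.472	-0.054	0.371	-0.561	-0.307	0.717	0.719	0.046	0.665	-0.214	0.834
D	0.855	0.019	0.243	-0.511	-0.262	-0.177	0.347	-1.062	-0.201	0.225	0.584	-0.824	0.045	0.485	-0.201	-0.365	-0.525	-1.003	0.765	0.087	-0.007	-0.432	0.378	1.142	0.29	-0.97	-0.315	-1.117	-0.684	0.985	-0.246	0.101	1.143	0.232	0.169	-1.299	0.024	0.534	0.448	-0.511
C	-0.407	-0.091	-0.854	-0.788	-0.008	0.396	0.326	-0.324	0.422	0.356	0.159	0.392	-0.069	-0.221	-0.579	-0.463	-0.116	0.242	-0.123	0.247	-0.345	-0.204	-0.738	-0.554	0.165	0.601	-0.152	0.43	0.473	0.257	-0.169	-0.944	-0.44	-0.473	0.132	0.765	-1.013	-0.201	0.967	-0.231
Q	-0.64	-0.928	-0.058	0.027	-0.755	0.014	-0.963	-1.075	0.509	1.229	0.531	-0.636	-0.052	0.216	-1.038	0.101	0.678	0.021	0.444	0.311	0.675	0.399	-0.679	-0.469	-0.189	-0.303	-0.493	0.679	-0.083	-0.845	0.146	0.196	-0.158	0.048	-1.108	-0.232	-0.185	-0.701	-0.179	0.398
E	0.55	-0.194	-0.143	-0.484	0.307	0.271	0.309	-0.136	0.484	0.54	0.313	0.349	0.151	-0.293	0.57	0.09	-0.299	-0.098	-0.516	0.127	-0.47	-0.78	0.773	0.179	0.505	0.377	0.699	-0.968	-0.178	-0.768	0.565	-0.382	0.042	-0.124	0.057	-0.192	-0.468	0.077	0.619	0.04
G	-0.384	0.34	-0.162	-0.245	0.287	0.8	0.72	0.368	0.106	0.052	0.085	0.026	-0.358	-0.383	0.649	0.341	-0.09	-0.068	0.278	0.501	0.011	-0.069	0.359	-0.13	0.752	-0.72	-0.12	0.024	-0.251	0.063	-1.497	-0.28	-0.56	-0.285	0.776	0.347	-0.301	-0.268	-0.171	-0.676
H	-0.479	-1.185	0.12	-0.256	0.005	0.657	0.121	0.539	-0.484	-0.268	-0.228	0.875	0.238	0.446	0.105	0.445	-0.253	0.408	0.84	0.17	-0.281	-0.047	0.117	-0.285	0.683	-0.35	0.115	0.192	-0.232	0.007	1.251	-0.068	-0.026	-0.451	-0.03	0.821	0.155	0.414	0.66	0.167
I	0.671	0.576	0.08	-0.99	-0.88	0.133	0.274	1.145	0.277	0.42	0.399	-0.395	-0.443	0.392	-0.297	0.055	0.1	0.046	-0.392	0.218	0.192	-0.202	-0.078	0.059	0.292	-0.219	0.723	-0.274	0.696	0.033	0.21	0.131	0.324	0.413	0.179	-0.026	0.705	0.085	-0.333	0.225
L	1.19	0.285	0.572	0.288	0.07	-0.975	0.266	0.498	-1.057	-0.306	0.128	-0.685	-0.067	-0.272	-0.029	-0.129	0.014	0.661	0.553	0.198	-0.999	-0.165	0.84	-0.126	0.171	-0.604	0.011	0	1.296	-0.577	0.671	-0.054	-0.384	0.136	-0.424	-0.358	0.259	-0.373	0.04	-0.694
K	0.06	0.634	0.1	-0.124	0.349	-0.628	0.163	0.299	-0.231	0.233	0.472	0.605	0.554	1.156	-0.104	0.197	-0.245	0.253	0.945	-0.593	0.109	-0.566	-0.208	-0.177	0.337	-0.143	0.171	0.446	-0.277	0.065	0.349	0.021	0.093	-0.38	-0.37	-0.318	0.453	-0.65	-0.865	0.159
M	0.427	-0.159	-0.298	0.057	0.654	-0.596	-0.036	0.42	0.608	-0.78	-0.765	-0.441	-0.104	-0.529	-0.376	1.112	-0.021	-0.173	-0.169	-0.29	-0.352	-0.464	-0.535	0.956	-0.445	0.591	0.667	0.336	-0.227	-0.353	-0.058	-0.956	0.717	-0.025	-0.076	0.315	0.247	-0.635	0.735	-0.014
F	-0.271	-0.238	-0.621	-0.451	0.47	0.198	-0.335	0.729	-0.261	-0.293	-0.082	-0.579	0.36	-0.381	0.254	-0.927	0.732	-0.011	0.605	-0.087	-1.208	0.13	0.516	0.304	0.251	-0.668	0.462	-0.265	-0.385	-0.434	-0.334	-0.343	-0.298	0.42	0.105	0.13	0.437	0.222	-0.471	0.464
P	0.392	0.267	0.035	-0.699	0.071	-0.128	0.195	0.176	-0.595	-0.135	-0.813	-0.398	0.107	0.475	-0.837	0.586	-1	-0.322	0.959	0.527	0.323	-0.299	0.284	0.407	0.733	0.201	0.345	-0.062	0.008	0.295	0.491	0.348	0.264	-0.015	-0.59	0.511	-0.069	0.285	0.016	0.112
S	-0.305	-0.188	0.868	0.208	-0.346	-0.346	-0.237	-0.479	0.341	-0.472	-0.34	-0.375	-0.798	-0.349	0.807	-0.571	0.078	-0.62	0.349	-1.203	1.047	0.141	-0.245	-0.764	-0.18	0.034	0.208	0.961	-0.789	0.678	0.265	-0.252	-1.07	-0.558	-0.431	-0.279	0.199	-0.097	-0.713	-0.017
T	-0.782	-0.013	0.981	0.351	-0.155	0.455	0.458	-0.384	0.015	-1.303	0.963	0.553	-0.22	-0.267	-0.093	0.568	-0.049	1.144	-0.479	-0.055	-0.089	-0.531	0.135	0.083	-0.723	-0.884	0.002	0.755	0.074	-0.118	-0.346	-0.481	-0.317	0.788	0.114	-0.207	-0.136	0.179	-0.211	0.138
W	0.095	0.085	-0.287	0.045	0.473	0.12	0.177	-0.519	-0.798	-0.243	-0.327	-0.003	-0.36	0.128	1.222	0.692	-0.05	-0.407	-0.359	-0.022	-1.229	-0.786	-0.388	0.129	-0.594	-1.033	-0.162	0.505	-0.658	0.086	-1.377	0.131	-0.152	0.373	-0.006	0.103	-0.796	-0.451	0.897	-0.256
Y	-0.744	0.432	0.4	0.112	-0.775	0.417	1.033	-0.964	-0.309	-0.043	0.17	-0.331	-1.035	-0.69	0.076	-0.393	-0.713	0.086	-0.959	-0.847	0.495	0.467	0.853	0.512	-0.415	-0.331	0.239	-0.307	-0.63	-0.133	0.275	-0.181	-0.398	-0.307	0.064	0.014	-0.273	-0.148	0.237	-0.595
V	0.393	0	0.135	0.13	0.913	-0.708	-0.467	-0.089	0.069	0.199	-0.01	-0.679	1.675	-0.136	-0.428	0.204	-0.839	0.39	-0.032	0.179	1.202	0.444	-0.163	-0.672	0.07	0.237	0.099	0.507	-0.37	0.045	0.431	0.471	0.8	0.349	0.146	-0.365	-0.491	-0.036	-0.219	0.479
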