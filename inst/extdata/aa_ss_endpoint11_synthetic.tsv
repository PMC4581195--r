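# SYNTHETIC stand-in for the 11-value secondary-structure segment-endpoint propensity amino-acid table.
# The canonical values live in the published literature and are not
# redistributed here; these deterministic placeholder values keep the
# feature pipeline runnable. Replace this file with a real table (same
# layout: residue row names, tab-separated numeric columns) via
# loadAminoAcidTables(path = <dir>).
res	v1	v2	v3	v4	v5	v6	v7	v8	v9	v10	v11
A	-1.255	-0.229	-0.432	0.461	-0.208	0.787	0.208	-0.575	0.806	-0.042	0.159
R	-0.811	-0.195	-0.142	-0.627	0.446	-0.503	-0.849	-0.106	-0.387	-0.421	0.158
N	-0.565	-0.867	0.399	0.333	0.517	-0.383	0.626	0.538	0.208	-0.752	0.546
D	-0.373	-0.213	-0.616	0.57	0.48	0.343	0.831	-0.165	-0.868	-0.033	0.056
C	0.014	-0.069	0.374	0.142	-0.043	-0.355	0.894	-0.292	0.249	0.507	0.653
Q	-0.279	-0.271	0.047	0.352	0.607	-0.223	-0.343	-0.203	1.003	-0.093	-0.63
E	0.065	-0.821	0.663	-0.353	-0.115	0.672	0.484	0.157	0.348	-0.713	-1.226
G	0.612	-0.354	-0.095	0.591	0.499	-0.085	0.037	0.057	0.554	0.769	-1.036
H	1.107	-0.557	0.05	0.809	-0.081	-0.383	-0.333	0.042	0.25	0.243	0.546
I	-0.359	-0.058	0.441	-0.12	-0.171	0.77	0.822	-0.333	0.195	0.161	-0.124
L	1.364	0.58	-0.735	-0.18	0.667	0.371	0.864	-0.586	0.438	0.37	-0.038
K	0.373	-0.179	0.56	-0.12	-0.161	-0.509	-0.646	0.102	-0.53	-0.211	-0.278
M	0.778	-0.668	-0.013	1.067	0.579	-0.231	0.75	-0.728	0.828	0.326	-0.754
F	-0.145	-0.314	0.035	-0.177	-0.222	-0.214	-0.79	0.523	-0.524	0.531	-0.224
P	-0.284	-0.375	-0.216	-0.3	-0.485	-0.39	-0.409	0.485	0.244	0.565	-0.347
S	0.236	-1.413	-0.102	-0.166	-0.01	-0.159	-0.271	0.012	-0.35	0.16	0.612
T	-1.061	0.098	-0.376	0.535	0.311	-0.383	-0.386	0.44	-0.408	-0.202	0.663
W	0.28	-0.228	0.946	0.204	0.038	-1.605	-0.598	0.458	0.659	0.119	-0.576
Y	-0.837	0.306	-0.02	-0.113	-0.825	-1.365	-0.292	-0.168	-1.057	-0.11	0.544
V	1.037	0.507	0.143	-0.461	-0.572	0.429	0.567	-0.805	0.468	0.553	-0.722
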