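# SYNTHETIC stand-in for the 7-value physico-chemical property amino-acid table.
# The canonical values live in the published literature and are not
# redistributed here; these deterministic placeholder values keep the
# feature pipeline runnable. Replace this file with a real table (same
# layout: residue row names, tab-separated numeric columns) via
# loadAminoAcidTables(path = <dir>).
res	v1	v2	v3	v4	v5	v6	v7
A	0.167	-0.159	0.175	0.05	0.189	0.584	-0.035
R	0.081	-1.066	-0.367	-0.293	0.187	-0.263	-1.002
N	0.197	-0.406	0.257	0.134	0.852	-0.305	-0.082
D	0.254	0.772	-0.05	-0.84	0.405	0.002	0.287
C	-0.477	0.618	-0.234	-0.935	0.709	0.607	-0.022
Q	0.592	0.235	0.247	0.261	-0.268	-0.422	0.206
E	-0.64	-0.281	-0.297	-0.455	0.234	-0.29	0.722
G	0.185	-0.054	-0.839	-0.884	-1.014	-0.246	-0.182
H	-0.726	-0.382	-0.859	-0.226	-0.378	-0.432	0.173
I	-0.722	-0.167	1.005	0.341	0.147	-0.364	0.073
L	0.811	-0.845	-0.197	-0.271	-0.476	-1.013	-0.067
K	-0.012	-1.011	-0.147	-0.186	-0.473	-0.101	0.205
M	0.87	0.506	0.074	1.145	0.144	0.081	0.062
F	0.108	0.83	-0.277	0.118	0.042	-0.875	-0.277
P	-0.388	0.989	-0.484	-1.022	1.16	-0.142	-0.454
S	-0.221	-0.215	0.138	0.904	-0.811	-0.496	0.065
T	0.56	-0.105	-1.29	-0.126	0.074	-0.566	0.734
W	-0.069	-0.152	0.381	-0.409	0.414	0.057	-0.823
Y	0.343	-0.597	-1.075	0.414	0.487	0.519	0.5
V	0.084	0.181	0.078	-0.713	0.708	0.539	0.42
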