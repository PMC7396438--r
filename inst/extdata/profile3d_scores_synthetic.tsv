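	E.helix	P1.helix	P2.helix	B1.helix	B2.helix	B3.helix	E.sheet	P1.sheet	P2.sheet	B1.sheet	B2.sheet	B3.sheet	E.other	P1.other	P2.other	B1.other	B2.other	B3.other
ALA	0.29	0.735	0.615	0.705	0.69	0.585	0.24	0.685	0.565	0.655	0.64	0.535	0.24	0.685	0.565	0.655	0.64	0.535
ARG	0.6	0.125	0.275	-0.205	-0.1	0.005	0.55	0.075	0.225	-0.255	-0.15	-0.045	0.55	0.075	0.225	-0.255	-0.15	-0.045
ASN	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099
ASP	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099
CYS	0.139	0.614	0.464	0.756	0.694	0.589	0.139	0.614	0.464	0.756	0.694	0.589	0.139	0.614	0.464	0.756	0.694	0.589
GLN	0.744	0.269	0.419	-0.061	0.044	0.149	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099
GLU	0.744	0.269	0.419	-0.061	0.044	0.149	0.694	0.219	0.369	-0.111	-0.006	0.099	0.694	0.219	0.369	-0.111	-0.006	0.099
GLY	0.531	0.667	0.694	0.337	0.442	0.364	0.531	0.667	0.694	0.337	0.442	0.364	0.531	0.667	0.694	0.337	0.442	0.364
HIS	0.738	0.263	0.413	-0.067	0.038	0.143	0.738	0.263	0.413	-0.067	0.038	0.143	0.738	0.263	0.413	-0.067	0.038	0.143
ILE	-0.15	0.325	0.175	0.655	0.55	0.445	-0.1	0.375	0.225	0.705	0.6	0.495	-0.15	0.325	0.175	0.655	0.55	0.445
LEU	0.001	0.476	0.326	0.806	0.701	0.596	-0.049	0.426	0.276	0.756	0.651	0.546	-0.049	0.426	0.276	0.756	0.651	0.546
LYS	0.687	0.212	0.362	-0.118	-0.013	0.092	0.637	0.162	0.312	-0.168	-0.063	0.042	0.637	0.162	0.312	-0.168	-0.063	0.042
MET	0.276	0.727	0.601	0.719	0.698	0.593	0.226	0.677	0.551	0.669	0.648	0.543	0.226	0.677	0.551	0.669	0.648	0.543
PHE	0.096	0.571	0.421	0.799	0.718	0.613	0.146	0.621	0.471	0.849	0.768	0.663	0.096	0.571	0.421	0.799	0.718	0.613
PRO	0.624	0.494	0.601	0.164	0.269	0.271	0.624	0.494	0.601	0.164	0.269	0.271	0.624	0.494	0.601	0.164	0.269	0.271
SER	0.562	0.609	0.663	0.279	0.384	0.333	0.562	0.609	0.663	0.279	0.384	0.333	0.562	0.609	0.663	0.279	0.384	0.333
THR	0.554	0.624	0.671	0.294	0.399	0.341	0.604	0.674	0.721	0.344	0.449	0.391	0.554	0.624	0.671	0.294	0.399	0.341
TRP	0.57	0.595	0.655	0.265	0.37	0.325	0.62	0.645	0.705	0.315	0.42	0.375	0.57	0.595	0.655	0.265	0.37	0.325
TYR	0.601	0.537	0.624	0.207	0.312	0.294	0.651	0.587	0.674	0.257	0.362	0.344	0.601	0.537	0.624	0.207	0.312	0.294
VAL	-0.107	0.368	0.218	0.698	0.593	0.488	-0.057	0.418	0.268	0.748	0.643	0.538	-0.107	0.368	0.218	0.698	0.593	0.488
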