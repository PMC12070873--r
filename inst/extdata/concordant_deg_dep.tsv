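gene	mrna_log2fc	mrna_p	prot_log2fc	prot_p	tissue
APOA1	3.188	0.014	0.278	0.048	ileum
APOA4	3.829	0.018	0.397	0.002	ileum
APOC3	4.853	0.055	0.337	0.001	ileum
ASS1	4.382	0.000	0.473	0.001	ileum
CDHR2	2.976	0.001	0.323	0.013	ileum
DAO	4.201	0.005	0.367	0.001	ileum
FABP1	3.445	0.004	0.598	0.036	ileum
FABP2	4.188	0.000	0.839	0.004	ileum
GSTA1	5.027	0.016	0.396	0.000	ileum
LOC100512780	3.109	0.008	0.363	0.038	ileum
LOC100738425	2.239	0.013	0.284	0.010	ileum
LOC100739663	4.240	0.024	0.321	0.026	ileum
LOC106509660	3.134	0.049	0.295	0.010	ileum
OAT	2.964	0.057	0.898	0.049	ileum
RBP2	4.029	0.041	0.513	0.002	ileum
REEP6	3.219	0.005	0.266	0.000	ileum
SDSL	5.510	0.024	0.531	0.000	ileum
SLC5A1	3.208	0.001	0.410	0.017	ileum
STARD4	2.373	0.014	0.287	0.019	ileum
ABHD5	1.133	0.002	0.798	0.000	liver
ARF4	2.604	0.000	0.498	0.011	liver
ARL1	1.267	0.000	0.734	0.023	liver
ATOX1	1.024	0.006	0.266	0.000	liver
ATP5F1E	1.147	0.005	0.352	0.000	liver
ATP5MC1	2.048	0.000	0.768	0.002	liver
ATP5PO	1.138	0.000	0.523	0.000	liver
CFL1	1.232	0.000	1.024	0.000	liver
COX5B	1.414	0.000	0.867	0.023	liver
COX6C	1.456	0.000	0.420	0.002	liver
COX7A2	1.632	0.000	0.413	0.023	liver
COX7C	1.245	0.000	0.419	0.001	liver
CYCS	1.577	0.000	0.304	0.023	liver
FKBP1A	1.146	0.000	0.641	0.001	liver
H2AFZ	1.127	0.000	0.337	0.048	liver
HBB	3.335	0.010	0.284	0.000	liver
HMOX1	1.150	0.001	1.082	0.000	liver
LDHB	1.354	0.003	0.358	0.001	liver
MIF	1.353	0.000	0.489	0.001	liver
NDUFA4	1.353	0.000	0.423	0.000	liver
NNMT	1.423	0.005	0.332	0.016	liver
NQO1	1.279	0.030	0.277	0.005	liver
PGK1	1.324	0.000	0.389	0.010	liver
PSMB6	1.314	0.000	0.283	0.001	liver
RTCB	1.345	0.000	0.343	0.000	liver
S100A11	1.063	0.013	1.012	0.000	liver
SLIRP	1.333	0.047	0.420	0.007	liver
TPI1	1.044	0.000	0.657	0.000	liver
UBE2D3	1.857	0.012	0.460	0.002	liver
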