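gene	log2fc	p	fdr	direction
RTL4	6.09	5.23e-7	5.95e-4	Up
ADTRP	5.43	3.75e-9	1.85e-5	Up
SDSL	5.36	5.81e-10	8.59e-6	Up
NTS	5.29	1.66e-8	6.12e-5	Up
KCTD8	5.24	6.22e-6	2.56e-3	Up
FEV	5.11	6.16e-4	2.91e-2	Up
AQP7	5.04	5.14e-6	2.29e-3	Up
MRO	5.03	7.80e-4	3.29e-2	Up
FGFBP1	5.01	1.20e-3	4.20e-2	Up
CXH4orf3	4.88	2.13e-9	1.58e-5	Up
C13H3orf62	-3.82	2.13e-4	1.64e-2	Down
IFNA1	-3.90	1.8e-3	4.94e-2	Down
LOC102165987	-4.08	7.27e-4	3.21e-2	Down
FAT2	-4.17	1.14e-3	4.10e-2	Down
AIRE	-4.24	1.15e-3	4.48e-2	Down
CDH8	-4.38	1.02e-3	3.84e-2	Down
PTPRQ	-4.82	1.54e-6	1.14e-3	Down
ITGB1BP2	-4.93	1.07e-3	3.96e-2	Down
LOC100624648	-5.89	9.34e-8	1.59e-4	Down
GRM8	-6.10	2.66e-5	5.54e-3	Down
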