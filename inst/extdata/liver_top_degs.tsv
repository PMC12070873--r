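gene	log2fc	p	fdr	direction
TCN1	5.48	3.14e-6	3.31e-4	Up
HBM	3.77	4.57e-4	1.20e-2	Up
HBB	3.31	2.23e-4	7.29e-3	Up
C2H11orf86	2.73	2.84e-7	5.26e-5	Up
LOC100737768	2.62	9.25e-4	1.98e-2	Up
ARF4	2.54	7.27e-14	3.59e-10	Up
PNPLA3	2.53	3.36e-5	1.84e-3	Up
LOC100517779	2.41	1.75e-7	3.45e-5	Up
APOA4	2.41	4.93e-7	8.21e-5	Up
SPATA22	2.39	1.78e-7	3.47e-5	Up
LOC102164346	-2.43	4.47e-5	2.25e-3	Down
CYP1A1	-2.44	1.99e-5	1.22e-3	Down
COLCA1	-2.46	2.95e-4	8.86e-3	Down
LOC110259967	-2.47	5.12e-5	2.47e-3	Down
GALP	-2.69	8.77e-4	1.90e-2	Down
LOC100154757	-3.01	1.77e-4	6.13e-3	Down
KCNH7	-3.14	1.14e-4	4.49e-3	Down
LOC110261964	-3.24	5.52e-4	1.37e-2	Down
ASIC1	-3.35	1.74e-4	6.08e-3	Down
CA3	-3.88	6.27e-5	2.87e-3	Down
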