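Locus	N	Na	Ne	I	Ho	He	F	PIC	PD	Nra
BPPCT001	885	15	4.1	1.81	0.5	0.76	0.34	0.73	0.92	8
BPPCT007	935	14	2.74	1.24	0.5	0.64	0.21	0.57	0.8	11
BPPCT015	871	11	2.24	1.15	0.37	0.55	0.34	0.5	0.75	9
BPPCT017	939	19	2.44	1.23	0.46	0.59	0.22	0.52	0.76	17
BPPCT038	949	13	2.38	1.21	0.44	0.58	0.24	0.53	0.77	10
CPDCT045	909	10	2.69	1.13	0.49	0.63	0.22	0.55	0.78	7
CPPCT006	921	9	2.47	1.03	0.44	0.6	0.26	0.53	0.77	6
EPPCU5176	948	12	2.84	1.24	0.5	0.65	0.23	0.59	0.82	9
UDP-005	841	15	2.36	1.21	0.4	0.58	0.3	0.54	0.78	11
UDP-022	894	8	3.01	1.32	0.42	0.67	0.38	0.63	0.85	4
UDP-409	926	10	1.74	0.88	0.32	0.42	0.24	0.4	0.64	7
UDP-412	932	12	3.35	1.45	0.53	0.7	0.24	0.66	0.87	8
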