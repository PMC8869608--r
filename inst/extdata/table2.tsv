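tdf_id	r1	r2	r3	r4	r5	flag
M1-A5-1	1.00	1.09	0.91	0.80	0.76	+
M1-A6-2	1.00	1.16	0.89	2.85	3.23	+
M1-A6-3	1.00	1.10	1.19	1.40	1.32	+
M1-A7-1	1.00	0.94	0.47	0.76	0.51	+
M1-A7-2	1.00	1.00	0.94	0.85	0.18	+
M1-A7-3	1.00	1.13	1.27	1.52	1.82	+
M1-A7-4	1.00	0.94	0.65	0.73	0.55	+
M1-A7-5	1.00	1.13	1.24	1.26	1.35	+
M1-A8-1	1.00	1.29	1.31	1.55	1.71	+
M1-A8-2	NO_BAND	NO_BAND	NO_BAND	NO_BAND	NO_BAND	-
M1-A9-1	1.00	1.02	1.06	1.24	1.23	+
M1-A9-2	1.00	1.11	0.86	0.92	1.03	-
M1-A9-3	1.00	0.91	1.04	1.23	1.27	-
M1-A10-1	1.00	0.76	0.65	0.40	0.36	+
M1-A10-2	1.00	1.44	2.91	3.42	3.81	+
M1-A10-3	1.00	1.03	1.27	1.40	2.03	+
M1-A11-1	1.00	0.95	0.75	0.75	0.74	+
M1-A11-2	NO_BAND	NO_BAND	NO_BAND	NO_BAND	NO_BAND	-
M1-A11-3	1.00	0.97	0.81	0.81	0.78	+
M1-A11-4	1.00	0.93	0.87	0.94	1.00	-
M1-A12-2	1.00	1.00	0.82	0.95	0.96	+
M2-A5-1	1.00	1.34	1.64	1.91	1.97	+
M2-A5-2	1.00	1.04	1.07	1.12	1.13	+
M2-A6-2	1.00	1.12	0.86	0.66	0.65	+
M2-A7-1	1.00	1.01	1.18	1.57	2.22	+
M2-A7-3	1.00	1.38	2.51	3.04	3.78	+
M2-A7-5	1.00	1.04	1.23	1.29	1.63	+
M2-A8-1	1.00	1.12	1.22	1.46	1.31	+
M2-A8-2	1.00	0.99	0.94	1.18	1.08	-
M2-A9-1	1.00	1.70	1.85	2.06	2.11	+
M2-A9-3	1.00	0.97	0.86	0.83	0.81	+
M2-A10-1	1.00	1.56	2.40	3.34	3.94	+
M2-A10-2	1.00	0.88	0.47	0.68	0.41	+
M2-A10-3	1.00	0.99	1.12	1.33	1.22	+
M3-A7-1	1.00	1.06	0.69	0.68	0.41	+
M3-A10-3	1.00	1.60	2.12	2.51	2.79	+
M3-A11-1	1.00	0.74	0.37	0.45	0.50	+
M9-A6-1	1.00	1.07	1.09	1.30	1.65	+
M9-A7-1	1.00	1.39	1.71	2.30	2.85	+
M9-A8-1	1.00	0.95	0.63	0.61	0.61	+
M9-A9-1	1.00	1.42	2.48	3.18	4.93	+
M9-A10-1	1.00	1.13	0.78	0.61	0.56	+
M9-A10-2	1.00	1.69	1.15	0.88	0.59	+
M9-A11-1	1.00	1.02	0.88	0.61	0.44	+
M9-A11-2	1.00	1.11	1.26	1.33	1.08	+
M9-A11-3	1.00	1.02	0.84	0.75	0.66	+
M9-A12-1	1.00	1.08	1.22	1.47	1.57	+
M10-A8-2	1.00	1.18	0.74	0.71	0.65	+
M10-A9-1	NO_BAND	NO_BAND	NO_BAND	NO_BAND	NO_BAND	-
M10-A9-3	1.00	0.96	0.79	0.77	0.76	+
M10-A10-1	1.00	1.13	1.42	1.70	2.05	+
M10-A11-1	1.00	1.11	0.62	0.51	0.33	+
M10-A11-2	1.00	0.78	0.48	0.40	0.20	+
M10-A12-1	1.00	1.56	1.69	2.45	2.47	+
M10-A12-2	1.00	1.12	0.62	0.59	0.55	+
M11-A7-1	1.00	1.14	1.57	1.59	1.80	+
M11-A8-1	1.00	0.88	0.58	0.55	0.46	+
M11-A8-2	1.00	1.32	1.69	2.25	2.20	+
M11-A9-1	1.00	0.89	0.67	0.65	0.57	+
M11-A9-2	1.00	1.07	0.77	0.77	0.66	+
M11-A10-1	1.00	1.18	1.15	1.16	1.19	-
M15-A5-1	1.00	1.25	1.61	1.77	2.27	+
M15-A8-1	1.00	1.46	1.85	2.03	2.48	+
M15-A8-4	1.00	1.03	1.18	1.36	1.67	+
M15-A9-1	1.00	0.78	0.51	0.49	0.49	+
M15-A10-1	1.00	2.09	1.61	1.49	1.19	-
M15-A10-3	1.00	1.06	1.27	1.45	1.66	+
M15-A10-4	1.00	0.98	0.61	0.64	0.40	-
M16-A5-1	1.00	0.80	0.58	0.55	0.51	+
M16-A6-1	1.00	1.06	1.12	1.51	1.72	+
M16-A7-1	1.00	1.12	1.07	1.41	2.23	-
M16-A8-1	1.00	1.30	1.41	1.69	1.20	+
M16-A9-1	1.00	0.56	0.76	1.03	1.22	-
M16-A9-2	1.00	0.99	0.85	0.68	0.49	+
M16-A10-1	1.00	0.94	0.71	0.65	0.44	+
M16-A10-2	1.00	1.07	1.23	1.54	1.88	+
M16-A11-1	1.00	0.85	0.70	0.62	0.61	+
M16-A11-2	1.00	1.12	1.14	1.22	1.15	+
M16-A12-1	1.00	0.81	1.10	1.22	2.04	-
M16-A12-3	1.00	0.83	0.52	0.50	0.47	+
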