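compound	position	center_or_range	pattern	J_list	n_protons	buckets_printed	span_rule
Stearic acid	2	2.27	t	7.4	2	2.30, 2.26	TRUE
Stearic acid	3	1.54-1.64	m		2	1.62, 1.58, 1.54	FALSE
Stearic acid	4-17	1.22-1.38	m		26	1.38, 1.34, 1.30, 1.26, 1.22	TRUE
Stearic acid	18	0.89	brt		3	0.94, 0.90, 0.86	FALSE
Oleic acid	9,10	5.34	m		2	5.38, 5.34, 5.30	FALSE
Oleic acid	2	2.27	t	7.4	2	2.30, 2.26	TRUE
Oleic acid	8,11	2.03	m		4	2.06, 2.02, 1.98	FALSE
Oleic acid	3	1.59	m		2	1.62, 1.58, 1.54	FALSE
Oleic acid	4-7,12-17	1.21-1.41	m		20	1.38, 1.34, 1.30, 1.26, 1.22	FALSE
Oleic acid	18	0.89	brt		3	0.94, 0.90, 0.86	FALSE
Linoleic acid	9-13	5.27-5.40	m		4	5.38, 5.34, 5.30, 5.26	FALSE
Linoleic acid	11	2.77	t	6.1	2	2.78, 2.74	TRUE
Linoleic acid	2	2.27	t	7.4	2	2.30, 2.26	TRUE
Linoleic acid	8,14	2.06	m		4	2.10, 2.06, 2.02	FALSE
Linoleic acid	3	1.59	m		2	1.62, 1.58, 1.54	FALSE
Linoleic acid	4-7,15-17	1.24-1.42	m		14	1.42, 1.38, 1.34, 1.26	FALSE
Linoleic acid	18	0.9	brt		3	0.94, 0.90, 0.86	FALSE
Sucrose	1'	5.38	d	3.8	1	5.38	TRUE
Sucrose	1a	3.63	d	12.1	1	3.62	FALSE
Sucrose	1b	3.59	d	12.1	1	3.58	FALSE
Sucrose	3	4.09	d	8.1	1	4.10, 4.06	TRUE
Sucrose	4	4.01	dd	8.1;7.9	1	4.02, 3.98	TRUE
Sucrose	3,5,6,5',6'	3.67-3.84	m		7	3.82, 3.78, 3.74, 3.70, 3.66	FALSE
Sucrose	2'	3.41	dd	9.8;3.8	1	3.42, 3.38	TRUE
Sucrose	4'	3.34-3.37	m		1	3.34	FALSE
Glucose	a-1	5.09	d	3.7	1	5.10	TRUE
Glucose	b-1	4.46	d	7.8	1	4.46	TRUE
Glucose	a-2	3.74-3.80	m		1	3.82, 3.78, 3.74	TRUE
Glucose	a-3	3.63-3.70	m		1	3.70, 3.66, 3.62	TRUE
Glucose	a-4	3.34	dd	3.7;9.5	1	3.34	TRUE
Glucose	b-2	3.10-3.14	m		1	3.14, 3.10	TRUE
6-Gingerol	6'	6.77	d	1.9	1	6.78, 6.74	FALSE
6-Gingerol	3'	6.68	d	8.0	1	6.70, 6.66	TRUE
6-Gingerol	2'	6.61	dd	8.0;1.9	1	6.62, 6.58	TRUE
6-Gingerol	5	3.99	m		1	4.02, 3.98	FALSE
6-Gingerol	OCH3	3.82	s		3	3.82	TRUE
6-Gingerol	1,2	2.77	brs		4	2.78	TRUE
6-Gingerol	4	2.45-2.59	m		2	2.58, 2.54, 2.50, 2.46	TRUE
6-Gingerol	6	1.39	m		2	1.42, 1.36	FALSE
6-Gingerol	7,8,9	1.21-1.35	m		6	1.38, 1.34, 1.30, 1.26	FALSE
6-Gingerol	10	0.9	t	6.7	3	0.94, 0.90, 0.86	FALSE
6-Shogaol	5	6.89	dt	15.9;7.0	1	6.94, 6.90, 6.86	TRUE
6-Shogaol	6'	6.77	d	1.9	1	6.78, 6.74	FALSE
6-Shogaol	3'	6.68	d	8.0	1	6.70, 6.66	TRUE
6-Shogaol	2'	6.61	dd	8.0;1.9	1	6.62, 6.58	TRUE
6-Shogaol	4	6.10	dt	15.9;1.5	1	6.10, 6.06	FALSE
6-Shogaol	OCH3	3.82	s		3	3.82	TRUE
6-Shogaol	1,2	2.78-2.94	m		2	2.90, 2.86, 2.82, 2.78	FALSE
6-Shogaol	6	2.22	m		2	2.26, 2.22, 2.18	FALSE
6-Shogaol	7	1.46	m		2	1.50, 1.46, 1.42	FALSE
6-Shogaol	8,9	1.25-1.38	m		4	1.34, 1.30, 1.26	FALSE
6-Shogaol	10	0.9	t	6.7	3	0.94, 0.90, 0.86	FALSE
alpha-Zingiberene	2	5.62	dd	9.9;3.0	1	5.62	TRUE
alpha-Zingiberene	3	1.88-2.07	m		1	2.06, 2.02, 1.98, 1.94	FALSE
alpha-Zingiberene	4	2.17-2.26	m		1	2.22, 2.18, 2.14	FALSE
alpha-Zingiberene	5	5.77	m		1	5.78, 5.74	FALSE
alpha-Zingiberene	6	5.42	brs		1	5.46, 5.42	FALSE
alpha-Zingiberene	7	1.48-1.58	m		1	1.58, 1.54, 1.50	TRUE
alpha-Zingiberene	8a	1.46	m		1	1.46, 1.42, 1.38	FALSE
alpha-Zingiberene	8b	1.12-1.22	m		1	1.22, 1.18, 1.14	TRUE
alpha-Zingiberene	9	1.97-2.07	m		1	2.06, 2.02, 1.98	TRUE
alpha-Zingiberene	10	5.10	m		1	5.14, 5.10, 5.06	FALSE
alpha-Zingiberene	12	1.60	s		3	1.62, 1.58	FALSE
alpha-Zingiberene	13	1.68	m		3	1.70, 1.66	FALSE
alpha-Zingiberene	14	0.88	d	6.9	3	0.90, 0.86	TRUE
alpha-Zingiberene	15	1.68	m		3	1.70, 1.66	FALSE
ar-Curcumene	2,6	7.07	d	8.3	2	7.10, 7.06	TRUE
ar-Curcumene	3,5	7.02	d	8.3	2	7.06, 7.02	FALSE
ar-Curcumene	7	2.62	sext	7.0	1	2.66, 2.62, 2.58	TRUE
ar-Curcumene	8	1.57	m		2	1.58, 1.54	FALSE
ar-Curcumene	9	1.78-1.90	m		2	1.86, 1.82	FALSE
ar-Curcumene	10	5.08	m		1	5.10, 5.06	FALSE
ar-Curcumene	12	1.48	brs		3	1.50, 1.46	FALSE
ar-Curcumene	13	1.65	d	1.1	3	1.66, 1.62	FALSE
ar-Curcumene	14	1.19	d	6.9	3	1.18	TRUE
ar-Curcumene	15	2.29	s		3	2.34, 2.30	FALSE
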