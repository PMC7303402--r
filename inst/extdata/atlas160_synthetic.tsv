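x	y	z	label	network
19	-22	37	ACC	cingulo-opercular
12	-30	41	Basal ganglia	cingulo-opercular
34	28	27	Basal ganglia	cingulo-opercular
41	25	7	Thalamus	cingulo-opercular
-31	31	14	vFC	cingulo-opercular
21	20	9	Basal ganglia	cingulo-opercular
9	-17	18	aPFC	cingulo-opercular
-12	38	-1	Precuneus	cingulo-opercular
24	-12	-6	Thalamus	cingulo-opercular
30	41	31	ACC	cingulo-opercular
22	6	42	Anterior insula	cingulo-opercular
18	-31	3	Precuneus	cingulo-opercular
29	-20	37	Precuneus	cingulo-opercular
0	-31	-6	aPFC	cingulo-opercular
7	21	7	aPFC	cingulo-opercular
43	30	21	Mid-insula	cingulo-opercular
-7	-12	3	Mid-insula	cingulo-opercular
22	7	-8	Mid-insula	cingulo-opercular
-27	42	23	vFC	cingulo-opercular
-40	32	32	Anterior insula	cingulo-opercular
-34	3	1	Temporal	cingulo-opercular
-2	35	7	vFC	cingulo-opercular
-33	-39	-8	Precuneus	cingulo-opercular
0	14	37	Anterior insula	cingulo-opercular
-27	1	34	Anterior insula	cingulo-opercular
37	-38	21	Anterior insula	cingulo-opercular
22	32	-2	Temporal	cingulo-opercular
2	-35	18	ACC	cingulo-opercular
45	-2	15	Precuneus	cingulo-opercular
-44	-15	4	Thalamus	cingulo-opercular
18	-37	10	Basal ganglia	cingulo-opercular
31	-9	0	Mid-insula	cingulo-opercular
-10	-6	29	IPL	fronto-parietal
7	-40	44	Post parietal	fronto-parietal
38	-41	39	vPFC	fronto-parietal
23	48	9	Post parietal	fronto-parietal
-19	-41	38	dlPFC	fronto-parietal
-40	39	41	dlPFC	fronto-parietal
-23	43	32	IPS	fronto-parietal
21	20	33	IPS	fronto-parietal
27	2	50	vPFC	fronto-parietal
-5	15	19	IPL	fronto-parietal
-2	-58	54	dFC	fronto-parietal
47	4	52	dlPFC	fronto-parietal
-6	46	55	IPS	fronto-parietal
-45	25	9	Post parietal	fronto-parietal
22	40	23	IPS	fronto-parietal
-28	21	15	IPL	fronto-parietal
6	23	49	dlPFC	fronto-parietal
-41	28	6	vPFC	fronto-parietal
38	22	53	aPFC	fronto-parietal
-47	36	41	IPS	fronto-parietal
15	10	48	vPFC	fronto-parietal
-45	-26	32	Inf temporal	default-mode
-43	11	-5	Inf temporal	default-mode
-30	-73	-4	Sup frontal	default-mode
-22	-34	-12	ACC	default-mode
-46	-74	-7	Angular gyrus	default-mode
-19	44	-11	Angular gyrus	default-mode
39	54	23	ACC	default-mode
15	-5	3	ACC	default-mode
-42	-37	21	Post cingulate	default-mode
-49	-49	27	Occipital	default-mode
-33	-18	15	Sup frontal	default-mode
-48	-63	3	vmPFC	default-mode
-11	-62	46	Sup frontal	default-mode
2	-65	47	ACC	default-mode
-45	46	-12	Precuneus	default-mode
16	-62	16	aPFC	default-mode
34	-15	-3	Precuneus	default-mode
34	-42	12	Sup frontal	default-mode
18	27	22	vmPFC	default-mode
-47	-27	-6	Inf temporal	default-mode
-13	14	12	aPFC	default-mode
3	40	23	Inf temporal	default-mode
13	-9	34	Occipital	default-mode
-16	38	-10	Precuneus	default-mode
-24	-43	30	Angular gyrus	default-mode
-32	-30	0	vmPFC	default-mode
-12	-57	32	aPFC	default-mode
-24	50	7	Inf temporal	default-mode
-25	16	10	aPFC	default-mode
-32	15	44	Angular gyrus	default-mode
-36	-48	48	Inf temporal	default-mode
-7	-20	6	ACC	default-mode
-46	41	-1	Inf temporal	default-mode
37	10	-15	Post cingulate	default-mode
58	11	14	Frontal	sensorimotor
60	8	34	dFC	sensorimotor
-55	7	23	vFC	sensorimotor
10	5	51	Pre-SMA	sensorimotor
43	1	12	vFC	sensorimotor
0	-1	52	SMA	sensorimotor
53	-3	32	Frontal	sensorimotor
58	-3	17	Precentral gyrus	sensorimotor
-42	-3	11	Mid-insula	sensorimotor
-44	-6	49	Precentral gyrus	sensorimotor
-26	-8	54	Parietal	sensorimotor
46	-8	24	Precentral gyrus	sensorimotor
-54	-9	23	Precentral gyrus	sensorimotor
44	-11	38	Precentral gyrus	sensorimotor
-47	-12	36	Parietal	sensorimotor
33	-12	16	Mid-insula	sensorimotor
-36	-12	15	Mid-insula	sensorimotor
59	-13	8	Temporal	sensorimotor
-38	-15	59	Parietal	sensorimotor
-47	-18	50	Parietal	sensorimotor
46	-20	45	Parietal	sensorimotor
-55	-22	38	Parietal	sensorimotor
-54	-22	22	Precentral gyrus	sensorimotor
-54	-22	9	Temporal	sensorimotor
41	-23	55	Parietal	sensorimotor
42	-24	17	Posterior insula	sensorimotor
18	-27	62	Parietal	sensorimotor
-38	-27	60	Parietal	sensorimotor
-24	-30	64	Parietal	sensorimotor
-41	-31	48	Posterior parietal	sensorimotor
-41	-37	16	Temporal	sensorimotor
-53	-37	13	Temporal	sensorimotor
34	-39	65	Superior parietal	sensorimotor
-6	-57	28	Occipital	occipital
20	-68	11	Fusiform	occipital
-39	-64	-7	Fusiform	occipital
4	-72	-2	Temporal	occipital
34	-90	10	Occipital	occipital
1	-58	10	Occipital	occipital
-31	-63	-4	Post occipital	occipital
36	-96	20	Occipital	occipital
-5	-59	-11	Post occipital	occipital
16	-68	20	Occipital	occipital
11	-98	6	Occipital	occipital
2	-94	24	Occipital	occipital
-29	-62	15	Fusiform	occipital
-4	-62	27	Fusiform	occipital
34	-95	7	Temporal	occipital
-23	-100	18	Occipital	occipital
-37	-63	24	Fusiform	occipital
-15	-59	3	Fusiform	occipital
33	-77	-2	Post occipital	occipital
33	-92	-10	Occipital	occipital
-11	-98	30	Fusiform	occipital
-32	-57	22	Post occipital	occipital
-28	-44	-25	Lateral cerebellum	cerebellum
-24	-54	-21	Lateral cerebellum	cerebellum
-37	-54	-37	Inferior cerebellum	cerebellum
-34	-57	-24	Lateral cerebellum	cerebellum
-6	-60	-15	Medial cerebellum	cerebellum
-25	-60	-34	Inferior cerebellum	cerebellum
32	-61	-31	Inferior cerebellum	cerebellum
-16	-64	-21	Medial cerebellum	cerebellum
21	-64	-22	Lateral cerebellum	cerebellum
1	-66	-24	Medial cerebellum	cerebellum
-34	-67	-29	Inferior cerebellum	cerebellum
-11	-72	-14	Medial cerebellum	cerebellum
33	-73	-30	Inferior cerebellum	cerebellum
5	-75	-11	Medial cerebellum	cerebellum
14	-75	-21	Medial cerebellum	cerebellum
-21	-79	-33	Inferior cerebellum	cerebellum
-6	-79	-33	Inferior cerebellum	cerebellum
18	-81	-33	Inferior cerebellum	cerebellum
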