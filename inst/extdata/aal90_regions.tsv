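index	label	name
1	Precentral_L	Left precentral gyrus
2	Precentral_R	Right precentral gyrus
3	Frontal_Sup_L	Left superior frontal gyrus, dorsolateral
4	Frontal_Sup_R	Right superior frontal gyrus, dorsolateral
5	Frontal_Sup_Orb_L	Left superior frontal gyrus, orbital part
6	Frontal_Sup_Orb_R	Right superior frontal gyrus, orbital part
7	Frontal_Mid_L	Left middle frontal gyrus
8	Frontal_Mid_R	Right middle frontal gyrus
9	Frontal_Mid_Orb_L	Left middle frontal gyrus, orbital part
10	Frontal_Mid_Orb_R	Right middle frontal gyrus, orbital part
11	Frontal_Inf_Oper_L	Left inferior frontal gyrus, opercular part
12	Frontal_Inf_Oper_R	Right inferior frontal gyrus, opercular part
13	Frontal_Inf_Tri_L	Left inferior frontal gyrus, triangular part
14	Frontal_Inf_Tri_R	Right inferior frontal gyrus, triangular part
15	Frontal_Inf_Orb_L	Left inferior frontal gyrus, orbital part
16	Frontal_Inf_Orb_R	Right inferior frontal gyrus, orbital part
17	Rolandic_Oper_L	Left rolandic operculum
18	Rolandic_Oper_R	Right rolandic operculum
19	Supp_Motor_Area_L	Left supplementary motor area
20	Supp_Motor_Area_R	Right supplementary motor area
21	Olfactory_L	Left olfactory cortex
22	Olfactory_R	Right olfactory cortex
23	Frontal_Sup_Medial_L	Left superior frontal gyrus, medial
24	Frontal_Sup_Medial_R	Right superior frontal gyrus, medial
25	Frontal_Med_Orb_L	Left superior frontal gyrus, medial orbital
26	Frontal_Med_Orb_R	Right superior frontal gyrus, medial orbital
27	Rectus_L	Left gyrus rectus
28	Rectus_R	Right gyrus rectus
29	Insula_L	Left insula
30	Insula_R	Right insula
31	Cingulum_Ant_L	Left anterior cingulate and paracingulate gyri
32	Cingulum_Ant_R	Right anterior cingulate and paracingulate gyri
33	Cingulum_Mid_L	Left median cingulate and paracingulate gyri
34	Cingulum_Mid_R	Right median cingulate and paracingulate gyri
35	Cingulum_Post_L	Left posterior cingulate gyrus
36	Cingulum_Post_R	Right posterior cingulate gyrus
37	Hippocampus_L	Left hippocampus
38	Hippocampus_R	Right hippocampus
39	ParaHippocampal_L	Left parahippocampal gyrus
40	ParaHippocampal_R	Right parahippocampal gyrus
41	Amygdala_L	Left amygdala
42	Amygdala_R	Right amygdala
43	Calcarine_L	Left calcarine fissure and surrounding cortex
44	Calcarine_R	Right calcarine fissure and surrounding cortex
45	Cuneus_L	Left cuneus
46	Cuneus_R	Right cuneus
47	Lingual_L	Left lingual gyrus
48	Lingual_R	Right lingual gyrus
49	Occipital_Sup_L	Left superior occipital gyrus
50	Occipital_Sup_R	Right superior occipital gyrus
51	Occipital_Mid_L	Left middle occipital gyrus
52	Occipital_Mid_R	Right middle occipital gyrus
53	Occipital_Inf_L	Left inferior occipital gyrus
54	Occipital_Inf_R	Right inferior occipital gyrus
55	Fusiform_L	Left fusiform gyrus
56	Fusiform_R	Right fusiform gyrus
57	Postcentral_L	Left postcentral gyrus
58	Postcentral_R	Right postcentral gyrus
59	Parietal_Sup_L	Left superior parietal gyrus
60	Parietal_Sup_R	Right superior parietal gyrus
61	Parietal_Inf_L	Left inferior parietal gyrus
62	Parietal_Inf_R	Right inferior parietal gyrus
63	SupraMarginal_L	Left supramarginal gyrus
64	SupraMarginal_R	Right supramarginal gyrus
65	Angular_L	Left angular gyrus
66	Angular_R	Right angular gyrus
67	Precuneus_L	Left precuneus
68	Precuneus_R	Right precuneus
69	Paracentral_Lobule_L	Left paracentral lobule
70	Paracentral_Lobule_R	Right paracentral lobule
71	Caudate_L	Left caudate nucleus
72	Caudate_R	Right caudate nucleus
73	Putamen_L	Left lenticular nucleus, putamen
74	Putamen_R	Right lenticular nucleus, putamen
75	Pallidum_L	Left lenticular nucleus, pallidum
76	Pallidum_R	Right lenticular nucleus, pallidum
77	Thalamus_L	Left thalamus
78	Thalamus_R	Right thalamus
79	Heschl_L	Left heschl gyrus
80	Heschl_R	Right heschl gyrus
81	Temporal_Sup_L	Left superior temporal gyrus
82	Temporal_Sup_R	Right superior temporal gyrus
83	Temporal_Pole_Sup_L	Left temporal pole: superior temporal gyrus
84	Temporal_Pole_Sup_R	Right temporal pole: superior temporal gyrus
85	Temporal_Mid_L	Left middle temporal gyrus
86	Temporal_Mid_R	Right middle temporal gyrus
87	Temporal_Pole_Mid_L	Left temporal pole: middle temporal gyrus
88	Temporal_Pole_Mid_R	Right temporal pole: middle temporal gyrus
89	Temporal_Inf_L	Left inferior temporal gyrus
90	Temporal_Inf_R	Right inferior temporal gyrus
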