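# Published cis-eQTL peak statistics for five GST genes across mapping
# panels (group BXD = C57BL/6J x DBA/2J recombinant inbred family; other
# groups are F2 or RI crosses between different parental strains).
# max_lrs and max_lod are the peak likelihood-ratio statistic and LOD
# score as published; additive is the published additive effect.
group	gene	tissue	max_lrs	max_lod	additive
BXD	Gsta4	Adipose	30.9	6.70	0.31
BXD	Gsta4	AdrenalGland	25.7	5.57	0.25
BXD	Gsta4	Cerebellum	10.4	2.26	0.19
BXD	Gsta4	Hippocampus	65.5	14.21	0.19
BXD	Gsta4	Hippocampus2	56.4	12.23	0.54
BXD	Gsta4	Liver	20	4.34	0.21
BXD	Gsta4	Liver2	18.9	4.10	0.48
BXD	Gsta4	Midbrain	48.5	10.52	0.08
BXD	Gsta4	Muscle	16.3	3.54	0.13
BXD	Gsta4	Neocortex	25.6	5.55	0.15
BXD	Gsta4	PituitaryGland	19.4	4.21	0.17
BHF2	Gsta4	Brain	15.9	3.45	0.02
BHF2	Gsta4	Liver	33.3	7.22	0.07
BXD	Gstt2	Eye	39.1	8.48	0.17
BXD	Gstt2	GastrointestinalTract	25.3	5.49	0.11
BXD	Gstt2	Hippocampus	18.8	4.08	0.08
BXD	Gstt2	Hippocampus2	14.3	3.10	0.09
BXD	Gstt2	Kidney	18.1	3.93	0.19
BXD	Gstt2	Lung	30.1	6.53	0.14
BXD	Gstt2	Midbrain	23.2	5.03	0.06
BXD	Gstt2	Neocortex	11.3	2.45	0.06
BXD	Gstz1	Hippocampus	13.5	2.93	0.06
BXD	Gstz1	Midbrain	80.2	17.40	0.10
BXD	Gstz1	NucleusAccumbens	16.5	3.58	0.08
BXD	Gstz1	PrefrontalCortex	21.1	4.58	0.11
AXBXA	Gstz1	Heart	23.7	5.14	-0.06
BHF2	Gstz1	Brain	69.7	15.12	0.03
CTB6F2	Gstz1	Brain	17.6	3.82	-0.02
CTB6F2	Gstz1	Liver	91.5	19.85	-0.11
CTB6F2	Gstz1	Muscle	59.1	12.82	-0.10
BXD	Gsto1	Amygdala	48.2	10.46	0.17
BXD	Gsto1	Brain	35.1	7.61	-0.13
BXD	Gsto1	Eye	15.1	3.28	-0.17
BXD	Gsto1	HematopoieticCells	16.5	3.58	-0.16
BXD	Gsto1	HematopoieticCells2	22.4	4.86	-0.25
BXD	Gsto1	Hippocampus	86.7	18.81	-0.17
BXD	Gsto1	Hippocampus2	34.7	7.53	-0.31
BXD	Gsto1	Hypothalamus	19.2	4.16	0.11
BXD	Gsto1	Kidney	29.1	6.31	-0.34
BXD	Gsto1	Liver	19.7	4.27	-0.13
BXD	Gsto1	Lung	44.5	9.65	-0.26
BXD	Gsto1	Midbrain	75.6	16.40	-0.10
BXD	Gsto1	Muscle	25.5	5.53	-0.14
BXD	Gsto1	Neocortex	27.9	6.05	-0.20
BXD	Gsto1	NucleusAccumbens	29	6.29	-0.08
BXD	Gsto1	PituitaryGland	62.2	13.49	-0.29
BXD	Gsto1	PrefrontalCortex	33.1	7.18	-0.14
BXD	Gsto1	PrefrontalCortex2	34.3	7.44	-0.16
BXD	Gsto1	Retina	21.7	4.71	-0.38
BXD	Gsto1	Spleen	27.9	6.05	-0.22
BXD	Gsto1	Spleen2	76.5	16.59	-0.27
BXD	Gsto1	Spleen3	56.1	12.17	-0.59
BXD	Gsto1	Striatum	14.4	3.12	-0.18
BXD	Gsto1	TCellRegulatory	41.6	9.02	-0.37
BXD	Gsto1	Brain2	27.4	5.94	-0.10
BXD	Gsto1	Liver2	47.7	10.35	-0.30
AXBXA	Gsto1	Liver	36	7.81	-0.18
AXBXA	Gsto1	Liver2	41.9	9.09	-0.25
LXS	Gsto1	Hippocampus	18.1	3.93	0.20
MDP	Gsto1	BoneFemur	22.6	4.90	-0.68
BXD	Mgst3	Adipose	21.8	4.73	0.19
BXD	Mgst3	Amygdala	23	4.99	0.11
BXD	Mgst3	Brain	31.4	6.81	0.22
BXD	Mgst3	Eye	22.8	4.95	0.20
BXD	Mgst3	GastrointestinalTract	27.9	6.05	-0.13
BXD	Mgst3	Hippocampus	81.6	17.70	0.35
BXD	Mgst3	Hippocampus2	75.8	16.44	0.94
BXD	Mgst3	Hippocampus3	85.6	18.57	0.85
BXD	Mgst3	Hypothalamus	13.2	2.86	0.11
BXD	Mgst3	Kidney	57	12.36	0.85
BXD	Mgst3	Liver	58.9	12.78	0.43
BXD	Mgst3	Liver2	47.3	10.26	0.81
BXD	Mgst3	Liver3	30.9	6.70	0.33
BXD	Mgst3	Midbrain	83.9	18.20	0.19
BXD	Mgst3	Muscle	46.6	10.11	0.16
BXD	Mgst3	Neocortex	53.7	11.65	0.33
BXD	Mgst3	Neocortex2	59	12.80	0.23
BXD	Mgst3	Neocortex3	66.4	14.40	0.31
BXD	Mgst3	NucleusAccumbens	47.4	10.28	0.30
BXD	Mgst3	PituitaryGland	33.7	7.31	-0.13
BXD	Mgst3	Retina	46.2	10.02	0.22
BXD	Mgst3	Spleen	15.9	3.45	0.29
BXD	Mgst3	Striatum	18.7	4.06	0.36
BXD	Mgst3	Striatum2	12.4	2.69	0.15
BXD	Mgst3	Striatum3	15.6	3.38	0.15
BXD	Mgst3	Striatum4	26.2	5.68	0.19
BXD	Mgst3	Brain2	37.6	8.16	0.32
BXD	Mgst3	Cerebellum	55.7	12.08	0.48
BXD	Mgst3	Cerebellum2	28.4	6.16	0.57
BXD	Mgst3	Liver4	71	15.40	0.58
B6D2F2	Mgst3	Brain	63.7	13.82	0.35
CTB6F2	Mgst3	Brain	323.4	70.15	0.13
CTB6F2	Mgst3	Liver	268	58.13	0.26
CTB6F2	Mgst3	Muscle	167.3	36.29	0.08
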