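# Published allele-specific expression validation table for GST genes in
# B6xD2 F1 hybrids: merged read counts per SNP (reference = B6 allele,
# alternative = D2 allele) with the published chi-square p-value and
# allelic ratio.  Counts are merged over concordant replicates, so each
# SNP appears as a single record (replicate_id = merged).
gene	chrom	pos	ref_base	alt_base	replicate_id	ref_count	alt_count	tissue	published_p	published_ratio
Gsta4	chr9	78192047	C	A	merged	317	699	Liver	0.00E+00	0.31
Gsta4	chr9	78192047	C	A	merged	72	165	Lung	0.00E+00	0.30
Gsta4	chr9	78192047	C	A	merged	86	161	Hip	1.82E-06	0.35
Gstz1	chr12	87164437	C	T	merged	3902	4007	Liver	2.38E-01	0.49
Gstz1	chr12	87164437	C	T	merged	139	153	Lung	4.13E-01	0.48
Gstz1	chr12	87164437	C	T	merged	96	117	Hip	1.50E-01	0.45
Gsto1	chr19	47855077	G	A	merged	281	208	Liver	9.63E-04	0.57
Gsto1	chr19	47857874	T	C	merged	511	393	Liver	8.69E-05	0.57
Gsto1	chr19	47858048	A	G	merged	464	300	Liver	3.02E-09	0.61
Gsto1	chr19	47864318	G	A	merged	1098	720	Liver	0.00E+00	0.60
Gsto1	chr19	47864511	G	A	merged	466	270	Liver	0.00E+00	0.63
Gsto1	chr19	47864609	T	C	merged	694	421	Liver	0.00E+00	0.62
Gsto1	chr19	47855077	G	A	merged	255	173	Lung	7.38E-05	0.60
Gsto1	chr19	47857874	T	C	merged	145	90	Lung	3.33E-04	0.62
Gsto1	chr19	47858048	A	G	merged	161	92	Lung	1.44E-05	0.64
Gsto1	chr19	47864318	G	A	merged	264	227	Lung	9.50E-02	0.54
Gsto1	chr19	47864511	G	A	merged	228	149	Lung	4.73E-05	0.60
Gsto1	chr19	47864609	T	C	merged	224	140	Lung	1.07E-05	0.62
Gsto1	chr19	47855077	G	A	merged	63	48	Hip	1.55E-01	0.57
Gsto1	chr19	47857874	T	C	merged	90	71	Hip	1.34E-01	0.56
Gsto1	chr19	47858048	A	G	merged	88	74	Hip	2.71E-01	0.54
Gsto1	chr19	47864318	G	A	merged	142	104	Hip	1.54E-02	0.58
Gsto1	chr19	47864511	G	A	merged	112	76	Hip	8.65E-03	0.60
Gsto1	chr19	47864609	T	C	merged	114	85	Hip	3.98E-02	0.57
Mgst3	chr1	167372500	A	G	merged	374	865	Liver	0.00E+00	0.30
Mgst3	chr1	167372500	A	G	merged	105	108	Lung	8.37E-01	0.49
Mgst3	chr1	167372500	A	G	merged	257	307	Hip	3.53E-02	0.46
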