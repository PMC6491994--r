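# Published per-SNP associations of five serum metabolites (exposure
# side of the two-sample MR analysis). 17 genome-wide-significant
# variants across acetate, pyruvate, valine, DHA and glycine.
# The rs261334 SE is printed with a stray minus sign in the source
# table; the positive value is stored here.
phenotype	chr	pos	rsid	effect_allele	other_allele	eaf	beta	se	pval	n
acetate	6	12042473	rs6933521	C	T	0.12	-0.092	0.016	8.10E-09	24742
pyruvate	2	27730940	rs1260326	C	T	0.64	-0.081	0.010	5.47E-16	22529
pyruvate	16	69979271	rs74249229	T	C	0.05	-0.153	0.023	2.13E-11	23561
valine	2	65208074	rs10211524	A	G	0.41	0.086	0.009	5.24E-20	24898
valine	4	89206230	rs9637599	C	A	0.47	0.114	0.009	1.67E-35	24899
valine	11	116661826	rs2072560	C	T	0.93	0.105	0.018	3.28E-09	24895
valine	17	7063667	rs7406661	C	T	0.24	0.079	0.013	5.35E-10	22659
dha	11	116651115	rs11604424	T	C	0.76	-0.083	0.018	7.84e-09	13495
dha	19	19667254	rs143988316	T	C	0.07	-0.150	0.026	1.10e-09	13494
dha	6	10990493	rs2281591	G	A	0.13	-0.108	0.003	3.66e-09	13498
dha	15	58726744	rs261334	C	G	0.77	-0.110	0.020	1.44e-13	13498
glycine	2	210439980	rs147007805	A	T	0.07	-0.140	0.024	8.05E-09	18732
glycine	2	211540507	rs1047891	A	C	0.33	0.487	0.011	1.00E-200	18730
glycine	3	125909669	rs1992855	C	T	0.41	0.062	0.011	5.60E-09	18733
glycine	8	9181395	rs2169387	G	A	0.87	-0.130	0.016	1.31E-16	18729
glycine	9	5934989	rs13298772	C	T	0.05	0.273	0.023	3.74E-33	18732
glycine	16	81065282	rs10083777	T	C	0.17	-0.106	0.015	2.97E-13	18732
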