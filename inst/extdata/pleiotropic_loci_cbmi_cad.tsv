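# Pleiotropic loci shared by childhood body-mass index (trait B) and
# coronary artery disease (trait A), as reported by a published cross-trait
# cFDR/GPA analysis of the two traits (ccFDR < 0.05 and fdr11 < 0.2).
# Columns: cfdr_A_given_B conditions CAD on CBMI, cfdr_B_given_A the
# reverse; ccfdr is the row-wise maximum; fdr11 is the GPA posterior
# probability of not being jointly associated.
chrom	snp_id	allele	role	gene	p_A	p_B	cfdr_A_given_B	cfdr_B_given_A	ccfdr	fdr11
16	rs9940128	G/A	intronic	FTO	1.67E-05	9.25E-14	1.67E-05	2.45E-11	1.67E-05	0.001527
2	rs1866146	G/A	UTR3	EFR3B	0.000594	2.04E-06	0.003264	0.000802	0.003264	0.031703
11	rs7127507	T/C	ncRNA_intronic	BDNF-AS	0.000754	1.29E-05	0.005024	0.003705	0.005024	0.053765
2	rs11125884	A/G	ncRNA_intronic	DNAJC27-AS1	0.01177	2.73E-13	0.01177	4.88E-10	0.01177	0.109489
1	rs7536226	C/T	intergenic	TSEN15, C1orf21	0.000247	5.31E-05	0.004194	0.015092	0.015092	0.064655
2	rs7420531	G/A	UTR3	AAK1	0.000533	8.77E-05	0.007644	0.021845	0.021845	0.088304
16	rs16969473	A/G	intronic	GPR139	0.002157	8.22E-05	0.018119	0.022945	0.022945	0.126129
19	rs13382133	C/T	intronic	FCHO1	7.67E-12	0.000558	1.1E-09	0.024548	0.024548	0.12562
13	rs12429545	G/A	intergenic	LINC01065, LINC00558	0.02676	3.66E-11	0.02676	7.68E-08	0.02676	0.175974
4	rs1996023	T/G	intergenic	GNPDA2, GABRG1	0.007574	2.73E-07	0.03787	0.00037	0.03787	0.094976
1	rs7531118	T/C	intergenic	NEGR1, LINC01360	0.01305	1.29E-05	0.03915	0.007047	0.03915	0.182283
16	rs194546	G/A	ncRNA_intronic	LOC101927814	0.006605	8.62E-06	0.03963	0.007183	0.03963	0.123251
2	rs17736503	G/T	intronic	NCOA1	0.007106	6.91E-05	0.04382	0.030049	0.04382	0.188942
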