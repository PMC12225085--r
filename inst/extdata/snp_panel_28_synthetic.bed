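# synthetic 28-SNP fingerprint panel: published rsIDs, synthetic coordinates/alleles/AFs
# chrom	start	end	rsid	ref	alt	pop_af
chr1	999	1000	rs969273	T	C	0.52
chr1	2499	2500	rs12446127	G	C	0.18
chr2	999	1000	rs16837903	C	G	0.55
chr2	2499	2500	rs12644477	A	G	0.21
chr3	999	1000	rs724710	T	G	0.58
chr3	2499	2500	rs2286615	G	T	0.24
chr4	999	1000	rs2233437	C	T	0.61
chr4	2499	2500	rs1642785	A	T	0.27
chr6	999	1000	rs1055088	T	A	0.64
chr6	2499	2500	rs2229974	G	A	0.30
chr9	999	1000	rs5759408	C	A	0.67
chr9	2499	2500	rs10263573	A	C	0.33
chr11	999	1000	rs1143685	T	C	0.70
chr11	2499	2500	rs1985791	G	C	0.36
chr12	999	1000	rs664982	C	G	0.73
chr12	2499	2500	rs1143686	A	G	0.39
chr15	999	1000	rs2009433	T	G	0.76
chr15	2499	2500	rs76433096	G	T	0.42
chr16	999	1000	rs1143689	C	T	0.79
chr16	2499	2500	rs12445580	A	T	0.45
chr17	999	1000	rs1071644	T	A	0.82
chr17	2499	2500	rs11865395	G	A	0.48
chr18	999	1000	rs1801018	C	A	0.85
chr18	2499	2500	rs4889430	A	C	0.51
chr20	999	1000	rs62218846	T	C	0.17
chr20	2499	2500	rs1805419	G	C	0.54
chr22	999	1000	rs738094	C	G	0.20
chr22	2499	2500	rs3747288	A	G	0.57
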