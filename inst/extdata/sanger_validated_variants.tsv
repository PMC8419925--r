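chrom	pos	ref	alt	genotype
chr1	78883942	C	T	1|0
chr1	78883952	ATATATATTTATCCTTTATATATATATTCTT	A	1|0
chr2	227913871	A	ATATCTATCTATC	1|0
chr2	227913885	G	A	1|0
chr2	227913889	G	A	1|0
chr2	227913928	T	TA	1|0
chr2	227913931	A	T	1|0
chr3	5336450	A	T,C	1|2
chr3	5336452	C	CGCGT	0|1
chr3	5336465	ACACACACACACG	A	0|1
chr3	5336477	GCA	G	1|0
chr3	5336487	A	G	0|1
chr6	160009985	C	CTTAA	0|1
chr6	160009986	C	A	0|1
chr6	167130970	G	GGGCCCCCCTCCCTCCGGGACTCCTCCCTCT	0|1
chr6	167130972	GA	G	1|0
chr6	167130973	A	G	0|1
chr6	167130976	A	C	1|1
chr6	167130986	T	C	1|0
chr6	167130989	A	G	1|1
chr6	167130990	C	A	1|0
chr6	167130992	C	T	1|0
chr9	134784949	C	T	0|1
chr9	134784951	G	T	0|1
chr9	134784955	GGGGGGGC	A	0|1
chr9	134784956	T	G	0|1
chr9	135663795	ACAGAGGGGGACCTGGAGGGGCAGAGGAGAGACCTGTGGGG	A	0|1
chr9	135663892	A	G	1|1
chr9	135663893	T	A,G	1|2
chr11	113466435	G	GC	1|1
chr11	113466437	A	T	1|1
chr12	100940063	A	AT	0|1
chr12	100940065	G	C	0|1
chr14	75318035	C	T	1|0
chr14	75318038	A	TA	1|0
chr14	75318052	T	C	1|0
chr14	75318054	T	G	1|0
chr20	11064571	T	TGA	0|1
chr20	11064574	A	ATTTTCAAGACTATTGTGACTATGAC	0|1
chr20	11064578	A	T	0|1
chr20	11064579	C	T	0|1
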