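# RHCE 15-SNP genotyping panel and the 16 known panel haplotypes (H01-H08, H10-H17).
# Positions are 1-based bp on microchromosome 23, genome build GRCg7b (carried as metadata).
# "-" marks a deleted span: PCR fails to amplify because the template is missing ("short"
# haplotypes H07, H12, H13, H16 lack the 3' portion of the gene, panel SNPs 8-15).
# H07 and H16 carry identical panel profiles; they are distinguishable only by provenance,
# not by this assay (see package documentation).
order_index	rsid	chrom	pos	exon	codon_change	aa_change	ref	alt	H01	H02	H03	H04	H05	H06	H07	H08	H10	H11	H12	H13	H14	H15	H16	H17
1	rs740623580	23	2749185	Exon 1	CGA>CAA	R9Q	G	A	G	G	G	G	A	G	G	G	G	G	G	G	G	G	G	G
2	rs869007872	23	2749241	Exon 1	TCT>TTT	S27F	C	T	C	T	T	C	C	C	C	T	C	C	T	T	C	T	C	T
3	rs794503708	23	2749275	Exon 1	CCC>CTC	P39L	C	T	C	T	T	C	C	C	C	T	C	C	T	T	C	T	C	T
4	rs733753324	23	2749792	Exon 2	TTG>TTC	L43F	G	C	G	C	G	G	G	G	G	G	G	G	C	G	G	C	G	G
5	rs731472668	23	2749926	Exon 2	CAT>CGT	H88R	A	G	A	G	A	A	A	A	A	G	A	A	G	A	G	G	A	A
6	rs738943348	23	2749941	Exon 2	CTG>CCG	L93P	T	C	T	C	T	T	T	T	T	C	T	T	C	T	C	C	T	T
7	rs739602946	23	2749952	Exon 2	TCA>CCA	S97P	T	C	T	C	T	T	T	T	T	C	T	T	C	T	C	C	T	T
8	rs738898886	23	2750212	Exon 3	ATA>ATG	I101M	A	G	A	G	A	A	A	A	-	G	A	A	-	-	A	G	-	A
9	rs313465722	23	2750348	Exon 3	TAT>CAT	Y147H	T	C	T	C	T	T	T	T	-	C	T	T	-	-	T	C	-	T
10	rs735870559	23	2751919	Exon 5	GTG>TTG	V215L	G	T	G	G	G	G	G	G	-	T	G	G	-	-	G	T	-	G
11	rs316593393	23	2752402	Exon 6	AAG>GAG	K272E	A	G	A	A	G	G	G	G	-	G	G	A	-	-	G	G	-	G
12	rs733511284	23	2752431	Exon 6	GGT>GGG	G281G	T	G	T	T	G	G	G	G	-	G	G	T	-	-	G	G	-	G
13	rs314800215	23	2752791	Exon 7	GAG>AAG	E325K	G	A	G	A	G	G	G	A	-	G	G	A	-	-	G	G	-	G
14	rs738163839	23	2752814	Exon 7	GAC>GAA	D332E	C	A	C	A	C	C	C	A	-	C	C	A	-	-	C	C	-	C
15	rs737604974	23	2753525	Exon 8	GAG>AAG	E343K	G	A	G	A	G	G	G	A	-	G	A	G	-	-	G	G	-	A
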