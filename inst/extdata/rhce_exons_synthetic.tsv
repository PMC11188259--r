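# SYNTHETIC 10-exon model of the RHCE gene on microchromosome 23, build galGal6
# coordinates (the build in which the deletion breakpoints 2,539,342-2,545,584 are
# reported). Exon boundaries are NOT the annotated ones (which are not published at
# base resolution in a transcribable form); they are constructed so that the deletion
# removes the last 43 codons (129 bp) of exon 3 and all of exons 4-10, matching the
# described gene anatomy. 1-based inclusive intervals.
gene_id	chrom	strand	exon	start	end
RHCE	23	+	1	2538000	2538150
RHCE	23	+	2	2538600	2538800
RHCE	23	+	3	2539100	2539470
RHCE	23	+	4	2539900	2540050
RHCE	23	+	5	2540500	2540650
RHCE	23	+	6	2541200	2541350
RHCE	23	+	7	2542000	2542160
RHCE	23	+	8	2542900	2543060
RHCE	23	+	9	2543800	2543950
RHCE	23	+	10	2544700	2545300
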