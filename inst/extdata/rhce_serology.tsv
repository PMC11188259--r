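# I-system serological allele associated with each RHCE panel haplotype, where known.
# A haplotype may serve more than one serological allele (H03 reacts as both I4 and I8;
# the I8 antiserum does not distinguish H01/H03/H04/H10).
haplotype	serological_alleles
H01	I8
H02	I2
H03	I4,I8
H04	I8
H10	I8
H11	I3
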