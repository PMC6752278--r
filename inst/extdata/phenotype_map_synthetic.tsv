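gene	allele1	allele2	phenotype
CYP2C19	*1	*1	Normal metabolizer
CYP2C19	*1	*2	Intermediate metabolizer
CYP2C19	*1	*3	Intermediate metabolizer
CYP2C19	*2	*2	Poor metabolizer
CYP2C19	*2	*3	Poor metabolizer
CYP2C19	*3	*3	Poor metabolizer
CYP2C19	*1	*17	Rapid metabolizer
CYP2C19	*2	*17	Intermediate metabolizer
CYP2C19	*3	*17	Intermediate metabolizer
CYP2C19	*17	*17	Ultrarapid metabolizer
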