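gene	action	targets	merged_label	reason
DPYD	merge_alleles	*9A,*9B	*9	suballeles differing only by a silent proxy variant
SLCO1B1	drop_allele	*30,*31		unknown function
CYP2D6	drop_structural_for_platform		 	copy number not detectable on this platform
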