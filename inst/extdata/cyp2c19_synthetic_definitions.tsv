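gene	label	function	structural	10:94781859:G:A:rs4244285	10:94775367:A:G:rs12248560	10:94780653:G:A:rs4986893
CYP2C19	*1	normal	none			
CYP2C19	*2	no_function	none	alt		
CYP2C19	*3	no_function	none			alt
CYP2C19	*17	increased	none		alt	
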