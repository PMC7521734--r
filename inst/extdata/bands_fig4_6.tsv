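strain	locus	size_bp	intensity	flags
Hm-105	ms-c25145	192	1	
Hm-105	ms-c25145	203	1	
Hm-105	ms-c25145	224	1	
Basel1	ms-c25145	205	1	
Basel1	ms-c25145	217	1	
Basel1	ms-c25145	220	1	
Basel2	ms-c25145	207	1	
AEP1	ms-c25145	218	1	
AEP1	ms-c25145	240	0.2	smear
AEP2	ms-c25145	218	1	
AEP2	ms-c25145	240	0.2	smear
Ho_CS	ms-c25145	218	1	
Ho_CS	ms-c25145	245	0.2	faint
Ho_CR	ms-c25145	218	1	
Ho_CR	ms-c25145	245	0.2	faint
Hm-105	ms-AIP	199	1	
Hm-105	ms-AIP	232	0.2	faint
Basel1	ms-AIP	198	1	
Basel2	ms-AIP	206	1	
reg-16	ms-AIP	199	1	
AEP1	ms-AIP	204	1	
AEP2	ms-AIP	204	1	
AEP2	ms-AIP	212	1	
AEP1	ms-DMTF1	104	1	
AEP1	ms-DMTF1	118	1	
AEP2	ms-DMTF1	104	1	
AEP2	ms-DMTF1	118	1	
endo-GFP	ms-DMTF1	104	1	
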