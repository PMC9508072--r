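gene	trait2	p_trait1	n1	p_trait2	n2	p_meta_published
BDNF	AD	4.22e-6	130644	1.08e-2	28757	2.75e-7
IZUMO1	AD	2.29e-5	130644	6.52e-3	28757	1.05e-6
FUT2	AD	3.37e-6	130644	1.02e-2	28757	2.10e-7
EP300	AD	1.18e-5	130644	9.72e-4	28757	1.36e-7
SPECC1	AD	8.28e-6	130644	1.99e-3	28757	1.51e-7
PPP2R2A	OD	2.95e-6	130644	9.82e-3	28709	1.78e-7
MED27	ND	6.47e-5	130644	1.425e-5	244890	8.64e-9
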