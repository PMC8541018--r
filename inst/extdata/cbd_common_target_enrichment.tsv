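term_name	members	p_value	fdr
thermoception	TRPA1,TRPM8,TRPV1	3.36e-09	3.20e-06
response to temperature stimulus	TRPA1,PPARG,TRPM8,TRPV4,TRPV1	8.35e-09	3.98e-06
ion transport	TRPA1,PPARG,TRPM8,GABRA5,HTR3A,TRPV4,TRPV1	5.60e-07	1.30e-04
cellular calcium ion homeostasis	TRPA1,TRPM8,GPR55,TRPV4,TRPV1	7.37e-07	1.40e-04
calcium ion transmembrane transport	TRPA1,TRPM8,TRPV4,TRPV1	1.84e-06	1.90e-04
response to cold	TRPA1,PPARG,TRPM8	1.97e-06	1.90e-04
detection of chemical stimulus involved in sensory perception of pain	TRPA1,TRPV1	3.52e-06	2.50e-04
chemical homeostasis	TRPA1,PPARG,TRPM8,GPR55,TRPV4,TRPV1	3.10e-06	2.50e-04
cannabinoid signaling pathway	CNR2,GPR55,FAAH	3.52e-06	2.50e-04
ion transmembrane transport	TRPA1,TRPM8,GABRA5,HTR3A,TRPV4,TRPV1	3.10e-06	2.50e-04
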