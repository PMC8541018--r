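symbol	vertex_degree	activity_nM	interaction_mode	source_ref
PPARG	572	100	full agonist	6
CNR2	294	34	partial agonist	7
GPR55	280	445	antagonist	8
TRPV1	274	1000	full agonist	9
HTR3A	194	329	negative allosteric modulator	10
TRPA1	148	110	full agonist	9
TRPV4	120	800	full agonist	9
GABRA5	100	1400	positive allosteric modulator	11
TRPM8	92	60	antagonist	9
FAAH	80	1520	inhibitor	9
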