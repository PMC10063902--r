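contrast	gene	regulated_type	p_value	position	residue	kegg_pathway	fisher_p
H/C	CACNA1D	Down	3.119E-05	802	S	Dopaminergic synapse	0.000058
S/H	CACNA1D	Up	1.507E-06	869	S	Dopaminergic synapse	0.000069
E/H	CACNA1D	Up	0.001828	1719	S	Dopaminergic synapse	0.000005
H/C	CACNA1A	Down	3.283E-05	2,200	S	Dopaminergic synapse	0.000058
S/H	CACNA1A	Up	4.527E-06	53	S	Dopaminergic synapse	0.000069
E/H	CACNA1A	Up	2.124E-05	53	S	Dopaminergic synapse	0.000005
H/C	CACNA1B	Down	1.637E-05	936	S	Dopaminergic synapse	0.000058
S/H	CACNA1B	Up	0.0015003	1951	S	Dopaminergic synapse	0.000069
S/H	CACNA1B	Up	0.0030467	915	S	Dopaminergic synapse	0.000069
E/H	CACNA1B	Up	0.001166	1951	S	Dopaminergic synapse	0.000005
E/H	CACNA1B	Up	0.0037351	915	S	Dopaminergic synapse	0.000005
E/H	CACNA1B	Up	0.0021289	892	S	Dopaminergic synapse	0.000005
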