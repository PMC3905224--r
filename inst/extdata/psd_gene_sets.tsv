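set	n_total	n_autosomal	description
hPSD_full	1461	1386	human postsynaptic density, proteins found in at least two pooled samples
hPSD_consensus	748	714	human postsynaptic density, proteins found in all three pooled samples
NMDA_RC	186	181	N-methyl-D-aspartate receptor complex and associated proteins
mGlu5_RC	52	50	metabotropic glutamate receptor 5 complex
AMPA_RC	9	7	AMPA receptor complex
ARC	28	25	activity-regulated cytoskeleton-associated protein complex
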