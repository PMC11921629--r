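# Curated subset of the Brenk et al. (ChemMedChem 2008) unwanted-moiety
# structural alert list: the most common reactive / pharmacokinetically
# undesirable motifs, rewritten as plain SMARTS for the OpenBabel engine.
# This is a subset, not the full published catalog of ~105 patterns.
name	smarts
nitro_group	[N+](=O)[O-]
azo_group	N=N
aldehyde	[CX3H1](=O)[#6]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
alkyl_halide	[CX4][Cl,Br,I]
epoxide	C1OC1
aziridine	C1NC1
michael_acceptor	[CX3]=[CX3][CX3]=O
isocyanate	N=C=O
thiol	[SX2H]
hydrazine	[NX3][NX3]
peroxide	[OX2][OX2]
quaternary_nitrogen	[NX4+]
nitroso	[NX2]=O
disulfide	[SX2][SX2]
sulfonate_ester	[#6]OS(=O)(=O)[#6]
polycyclic_aromatic	c1ccc2cc3ccccc3cc2c1
imine	[CX3]=[NX2]
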