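# Curated subset of the PAINS (pan-assay interference) filters of Baell &
# Holloway (J Med Chem 2010): representative members of the largest filter
# families, rewritten as plain SMARTS for the OpenBabel engine.  This is a
# subset, not the full published catalog of ~480 patterns.
name	smarts
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
catechol	Oc1ccccc1O
rhodanine	S=C1NC(=O)CS1
hydroxyphenyl_hydrazone	C=NNc1ccccc1
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C
azo_aromatic	cN=Nc
ene_one_ene	C=CC(=O)C=C
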