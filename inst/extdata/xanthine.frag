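# Fragment grammar for synthetic compound generation.
# Lines: core <TAB> SMILES with {R1} (and optionally {R2}) placeholders
#        sub  <TAB> substituent SMILES fragment (attached verbatim)
# Cores are purine/xanthine-like heteroaromatic scaffolds rich in
# hydrogen-bond acceptors, plus simpler aromatic controls.
core	Cn1c(=O)c2c(ncn2{R1})n(C)c1=O
core	Cn1c(=O)c2c(nc({R2})n2{R1})n(C)c1=O
core	Nc1nc(=O)c2c(ncn2{R1})[nH]1
core	O=c1[nH]c(=O)c2c(ncn2{R1})[nH]1
core	{R1}c1ccc2ncnc(N{R2})c2c1
core	{R1}c1ccccc1O
sub	C
sub	CC
sub	CCC
sub	CCO
sub	CC(C)C
sub	Cc8ccccc8
sub	CCc8ccccc8
sub	CC(=O)O
sub	CCN(C)C
sub	CCOC
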