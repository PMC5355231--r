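id	smiles	onbits
benzene	c1ccccc1	162,163,165
ethanol	CCO	82,109,114,139,153,155,157,160,164
aspirin	CC(=O)Oc1ccccc1C(=O)O	89,113,123,126,127,136,139,140,143,144,146,150,152,154,157,159,160,162,163,164,165
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	37,38,65,75,77,79,80,83,85,89,92,93,95,96,97,98,101,105,106,110,113,117,120,121,122,127,136,137,141,142,143,144,148,149,150,154,156,158,159,160,161,162,163,164,165
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O	74,115,123,139,141,149,154,155,157,159,160,162,163,164,165
paracetamol	CC(=O)Nc1ccc(O)cc1	92,110,113,117,127,131,133,135,139,143,151,152,154,156,157,158,159,160,161,162,163,164,165
glucose	OCC1OC(O)C(O)C(O)C1O	53,54,57,72,82,89,90,91,98,109,123,127,131,132,137,139,140,143,146,150,152,153,155,157,159,163,164,165
naphthalene	c1ccc2ccccc2c1	101,105,145,162,163,165
pyridine	c1ccncc1	65,98,121,137,161,162,163,165
imidazole	c1c[nH]cn1	65,77,79,83,96,120,121,137,142,151,161,162,165
cyclohexane	C1CCCCC1	118,128,129,147,163,165
toluene	Cc1ccccc1	160,162,163,165
phenol	Oc1ccccc1	113,127,139,143,152,157,162,163,164,165
aniline	Nc1ccccc1	84,133,135,151,156,158,161,162,163,165
nitrobenzene	O=[N+]([O-])c1ccccc1	24,49,56,63,70,71,94,102,119,122,124,130,133,135,148,156,158,159,161,162,163,164,165
benzoic_acid	OC(=O)c1ccccc1	123,139,154,157,159,162,163,164,165
acetone	CC(C)=O	74,149,152,154,160,164
dmso	CS(=O)C	51,60,61,67,73,74,86,88,93,102,124,148,149,160,164
urea	NC(N)=O	37,43,77,84,106,110,117,131,142,151,154,156,158,161,164
glycine	NCC(=O)O	54,82,84,95,100,104,123,131,132,139,151,153,154,155,157,158,159,161,164
cysteine	NC(CS)C(=O)O	53,54,82,84,88,90,95,104,111,123,131,139,151,153,154,155,156,157,158,159,161,164
fluorouracil	Fc1c[nH]c(=O)[nH]c1=O	37,42,43,53,65,77,80,87,89,92,97,98,106,107,110,113,117,120,121,127,131,134,136,137,142,143,144,150,151,154,156,159,161,162,163,164,165
doxorubicin_core	COc1cccc2C(=O)c3c(O)c4CC(O)(CC(O)c4c(O)c3C(=O)c12)C(=O)CO	53,66,72,82,89,90,91,93,101,104,105,109,112,113,126,127,128,129,131,132,136,139,140,143,144,145,146,152,153,154,155,157,159,160,162,163,164,165
cisplatin_ligand	NCCN	54,79,82,84,100,104,111,118,131,138,142,147,151,153,155,158,161
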