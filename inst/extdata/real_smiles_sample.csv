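name,smiles
acrylonitrile,C=CC#N
benzene,c1ccccc1
vinyl chloride,C=CCl
formaldehyde,C=O
ethylene oxide,C1CO1
nitrosodimethylamine,CN(C)N=O
benzidine,Nc1ccc(-c2ccc(N)cc2)cc1
aniline,Nc1ccccc1
nitrobenzene,O=[N+]([O-])c1ccccc1
trichloroethylene,ClC=C(Cl)Cl
carbon tetrachloride,ClC(Cl)(Cl)Cl
1-3-butadiene,C=CC=C
styrene,C=Cc1ccccc1
phenol,Oc1ccccc1
ethanol,CCO
acetic acid,CC(=O)O
glucose,OCC1OC(O)C(O)C(O)C1O
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
aspirin,CC(=O)Oc1ccccc1C(=O)O
urea,NC(N)=O
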