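# Default ligand exclusion list: water, common buffers, cryoprotectants,
# detergents, salts and lone ions that never define a binding site.
# One HET code per line; '#' starts a comment. Edit freely.
HOH
DOD
WAT
H2O
SO4
PO4
GOL
EDO
PEG
PG4
PGE
P6G
1PE
ACT
ACY
DMS
MPD
TRS
EPE
MES
FMT
CIT
FLC
TLA
TAR
NO3
BME
MRD
IMD
SCN
AZI
BCT
CO3
NH4
# lone ions
CL
BR
IOD
F
NA
K
LI
CS
MG
CA
ZN
MN
FE
FE2
NI
CU
CU1
CO
CD
SR
BA
HG
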