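# Hetero residue names never treated as candidate allosteric modulators:
# crystallisation buffers, cryo-protectants, detergents, single ions.
SO4
PO4
GOL
EDO
PEG
PG4
ACT
DMS
MPD
TRS
MES
EPE
FMT
CIT
NO3
CO3
BME
IMD
NAG
CL
BR
IOD
F
NA
K
MG
CA
ZN
MN
FE
FE2
NI
CU
CO
CD
HG
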