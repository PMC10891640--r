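term,coefficient
intercept_as_printed,1.216e3
ALogP,2.100e-3
AATSC5m,-6.597e-4
MATS5c,-1.453e-2
MATS4s,6.744e-2
GATS5m,5.535e-3
SCH-6,-3.136e-2
VCH-5,2.516e-2
minHBd,-2.316e-2
minHBint7,3.159e-3
nAtomLC,-1.681e-3
nFRing,1.964e-3
nT10HeteroRing,8.021e-3
RDF40m,7.442e-4
RDF45m,3.947e-6
RDF85m,4.102e-5
RDF115e,1.163e-5
E3m,-9.327e-3
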