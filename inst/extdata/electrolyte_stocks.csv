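stock,ssf_ml,sgf_ml,sif_ml
KCl 0.5 M,15.1,6.9,6.8
KH2PO4 0.5 M,3.7,0.9,0.8
NaHCO3 1 M,6.8,7.2,5.26
NaCl 2 M,0,11.8,9.6
MgCl2(H2O)6 0.15 M,0.5,0.4,1.1
(NH4)2CO3 0.5 M,0.06,0.5,0
HCl 6 M,0.49,1.3,0.7
H2O,373.35,371,375.74
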