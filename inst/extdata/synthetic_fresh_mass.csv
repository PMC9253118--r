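genotype,treatment,replicate,mass
WT,control,1,0.102
WT,control,2,0.098
WT,control,3,0.104
WT,stressed,1,0.055
WT,stressed,2,0.061
WT,stressed,3,0.058
OE,control,1,0.101
OE,control,2,0.099
OE,control,3,0.103
OE,stressed,1,0.031
OE,stressed,2,0.035
OE,stressed,3,0.028
KO,control,1,0.100
KO,control,2,0.103
KO,control,3,0.097
KO,stressed,1,0.078
KO,stressed,2,0.083
KO,stressed,3,0.074
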