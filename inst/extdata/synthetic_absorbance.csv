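sample_id,genotype,treatment,od663,od645,dilution,fm
s01,WT,control,0.82,0.31,10,0.105
s02,WT,control,0.79,0.30,10,0.098
s03,WT,control,0.85,0.33,10,0.101
s04,WT,stressed,0.41,0.16,10,0.092
s05,WT,stressed,0.38,0.15,10,0.095
s06,WT,stressed,0.44,0.17,10,0.099
s07,OE,control,0.80,0.31,10,0.100
s08,OE,control,0.83,0.32,10,0.104
s09,OE,control,0.78,0.30,10,0.097
s10,OE,stressed,0.22,0.09,10,0.090
s11,OE,stressed,0.25,0.10,10,0.094
s12,OE,stressed,0.20,0.08,10,0.091
s13,KO,control,0.81,0.31,10,0.102
s14,KO,control,0.84,0.32,10,0.099
s15,KO,control,0.80,0.31,10,0.103
s16,KO,stressed,0.61,0.24,10,0.096
s17,KO,stressed,0.58,0.22,10,0.093
s18,KO,stressed,0.64,0.25,10,0.098
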