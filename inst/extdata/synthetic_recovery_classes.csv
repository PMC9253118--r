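genotype,class,count
WT,full,6
WT,partial,8
WT,none,6
OE,full,2
OE,partial,5
OE,none,13
KO,full,12
KO,partial,6
KO,none,2
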