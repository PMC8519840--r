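amino_acid	proportion
arginine	0.11
histidine	0.05
isoleucine	0.10
leucine	0.16
lysine	0.15
methionine	0.04
phenylalanine	0.09
threonine	0.10
tryptophan	0.03
valine	0.17
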