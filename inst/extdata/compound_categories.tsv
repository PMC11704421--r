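compound	category
l-alanine	amino_acid
l-arginine	amino_acid
l-asparagine	amino_acid
l-aspartate	amino_acid
aspartate	amino_acid
l-cysteine	amino_acid
cysteine	amino_acid
l-glutamate	amino_acid
l-glutamine	amino_acid
l-glycine	amino_acid
glycine	amino_acid
l-histidine	amino_acid
histidine	amino_acid
l-isoleucine	amino_acid
l-leucine	amino_acid
leucine	amino_acid
l-lysine	amino_acid
lysine	amino_acid
l-methionine	amino_acid
methionine	amino_acid
l-phenylalanine	amino_acid
l-proline	amino_acid
l-serine	amino_acid
serine	amino_acid
l-threonine	amino_acid
threonine	amino_acid
l-tryptophan	amino_acid
tryptophan	amino_acid
l-tyrosine	amino_acid
l-valine	amino_acid
homoserine	amino_acid
l-homoserine	amino_acid
thiamine	vitamin
riboflavin	vitamin
nicotinate	vitamin
nicotinamide	vitamin
pantothenic acid	vitamin
pantothenate	vitamin
pyridoxine	vitamin
biotin	vitamin
folate	vitamin
inositol	vitamin
choline	vitamin
adenine	base
guanine	base
cytosine	base
uracil	base
thymine	base
hypoxanthine	base
xanthine	base
ergosterol	other
heme	other
heme a	other
glutathione	other
d-glucosamine	other
spermidine	other
spermine	other
putrescine	other
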