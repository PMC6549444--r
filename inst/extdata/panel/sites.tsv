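segment	label	position	alleles	meanings
COIB	mCOI1125Y	1125	CT	C=corn;T=rice
COIB	mCOI1164D	1164	AGT	A=corn;G=corn;T=rice;C=unobserved
COIB	mCOI1176Y	1176	CT	C=corn;T=rice
COIB	mCOI1182Y	1182	CT	C=corn;T=rice
COIB	mCOI1197R	1197	AG	A=corn;G=rice
COIB	mCOI1216W	1216	AT	A=corn;T=rice
COIB	mCOI1287R	1287	AG	A=h-config;G=h-config
TpiE4	gTpi129C	129	CT	T=consensus;C=variant
TpiE4	gTpi144G	144	AG	A=consensus;G=variant
TpiE4	gTpi165Y	165	CT	C=corn;T=rice
TpiE4	gTpi168Y	168	CT	C=corn;T=rice
TpiE4	gTpi180C	180	CT	T=consensus;C=variant
TpiE4	gTpi183Y	183	CT	C=corn;T=rice
TpiE4	gTpi192Y	192	CT	C=haplotype;T=haplotype
TpiE4	gTpi198Y	198	CT	C=haplotype;T=haplotype
TpiI4	gTpiI4[131]R	131	AG	G=consensus;A=minor
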