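collection	country	year	source_type	n
BUR	Burundi	2016-17	larva	38
CAR	Central African Republic	2017	larva	33
CHA	Chad	2017	larva	19
GHA	Ghana	2016	larva	44
nDRC	DR Congo (Sud-Ubangi)	2017	larva	27
sDRC	DR Congo (Haut-Katanga)	2017	larva	72
KEN	Kenya	2017	larva	55
SAf	South Africa	2017	larva	74
STP	Sao Tome and Principe	2016	larva	22
TAN	Tanzania	2017	larva	69
TOGa	Togo	2016	larva	89
TOGb	Togo (Lome)	2017	male_trap	340
ZAM	Zambia	2017	larva	74
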