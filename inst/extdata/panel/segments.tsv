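name	coordinate_origin	origin_offset	expected_length
COIB	predicted translational start of COI	870	603
TpiE4	5' start of exon 4	1	199
TpiI4	5' start of intron 4	10	163
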