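species	tag
T. cristatus	ACACTACTCGT
T. cristatus	ACGACACGTAT
C. asper	ACGAGTAGACT
C. asper	ACGCGTCTAGT
L. helveticus	ACGTACACACT
L. helveticus	ACGTACTGTGT
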