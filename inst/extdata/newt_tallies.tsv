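species	n_reads	n_repeat_reads	n_candidates	ntpp	sipl
T. cristatus	19562	936	107	41	11
C. asper	52075	1083	316	41	20
L. helveticus	55626	1434	319	22	15
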