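individual	population	locus	allele1	allele2
ind01	popA	LocA	150	150
ind02	popA	LocA	150	150
ind03	popA	LocA	150	150
ind04	popA	LocA	150	154
ind05	popA	LocA	150	154
ind06	popB	LocA	150	154
ind07	popB	LocA	150	154
ind08	popB	LocA	154	154
ind09	popB	LocA	154	154
ind10	popB	LocA	154	154
ind01	popA	LocB	200	200
ind02	popA	LocB	200	200
ind03	popA	LocB	200	200
ind04	popA	LocB	200	200
ind05	popA	LocB	200	200
ind06	popB	LocB	200	200
ind07	popB	LocB	200	200
ind08	popB	LocB	200	200
ind09	popB	LocB	200	200
ind10	popB	LocB	200	200
ind01	popA	LocC	180	184
ind02	popA	LocC	180	188
ind03	popA	LocC	184	188
ind04	popA	LocC	180	180
ind05	popA	LocC	184	184
ind06	popB	LocC	188	188
ind07	popB	LocC	180	184
ind08	popB	LocC	180	188
ind09	popB	LocC
ind10	popB	LocC	184	188
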