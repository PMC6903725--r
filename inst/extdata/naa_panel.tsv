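sample	group	tufted	tail_status	sex
NAA01	NAA	tufted	rumpless	M
NAA02	NAA	tufted	rumpless	M
NAA03	NAA	clean	rumpless	U
NAA04	NAA	tufted	rumpless	F
NAA05	NAA	clean	tailed	M
NAA06	NAA	tufted	rumpless	M
KA01	KA	clean	tailed	U
KA02	KA	clean	tailed	U
KA03	KA	clean	tailed	U
KD01	KD	clean	tailed	U
KD02	KD	clean	tailed	U
KD03	KD	clean	tailed	U
WL01	WL	clean	tailed	U
WL02	WL	clean	tailed	U
WL03	WL	clean	tailed	U
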