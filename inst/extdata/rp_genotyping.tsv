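phenotype	sv1	sv2	n
tailed_araucana	A/A	A/A	18
tailed_wildtype	A/A	A/A	42
partial	A/C	A/C	19
partial	A/C	C/C	2
rumpless	A/C	A/C	26
rumpless	C/C	C/C	32
rumpless	C/C	A/C	3
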