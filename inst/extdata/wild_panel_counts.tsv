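species	description	n
Or	Oryza rufipogon	101
On	Oryza nivara	16
Ob	Oryza barthii	15
Ol	Oryza longistaminata	6
Om	Oryza meridionalis	1
Oglu	Oryza glumaepatula	1
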