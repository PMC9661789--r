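group	description	n
DW	deepwater rice	37
SW	swamp rice	12
TW	tidal wetland rice	3
IR	irrigated rice	316
RL	rainfed lowland rice	191
UP	upland rice	308
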