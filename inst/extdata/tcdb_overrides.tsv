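profile	tcdb_family	tc_number
PF00909	Amt	1.A.11
PF00654	ClC	2.A.49
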