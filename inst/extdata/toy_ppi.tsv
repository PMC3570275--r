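# toy PPI fixture: amyloid trio plus angiogenin and its seven first neighbours
a	b
A2M	APOE
APOE	APP
ANG	ACTC1
ANG	ACTN2
ANG	ATP6AP1
ANG	PTEN
ANG	RNH1
ANG	TDGF1
ANG	TNFSF8
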