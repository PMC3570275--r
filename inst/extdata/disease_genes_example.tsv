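# small synthetic disease-gene association example
disease	gene	evidence
Alzheimer disease	APP	ex1
Alzheimer disease	APOE	ex2
Alzheimer disease	PSEN1	ex3
Amyotrophic lateral sclerosis	ANG	ex4
Amyotrophic lateral sclerosis	SOD1	ex5
Frontotemporal dementia	APP	ex6
Frontotemporal dementia	MAPT	ex7
Parkinson disease	SNCA	ex8
Parkinson disease	MAPT	ex9
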