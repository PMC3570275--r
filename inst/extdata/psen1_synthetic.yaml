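# Synthetic structure-only pathway fixture around presenilin-1 signalling.
# Matches sgpnet::psen1_pathway_synthetic(); not a curated pathway.
name: PSEN1_signalling_synthetic
members:
- id: APP
  species: protein
  location: membrane
- id: Ca2+
  species: signal
  location: ER
- id: CAM
  species: protein
  location: cytoplasm
- id: NICD
  species: protein
  location: nucleus
- id: NOTCH1
  species: gene
  location: nucleus
- id: PSEN1
  species: protein
  location: ER
- id: gamma_secretase
  species: protein
  location: membrane
interactions:
- class: prot_prot
  from: PSEN1
  to: gamma_secretase
  sign: activation
- class: prot_prot
  from: gamma_secretase
  to: APP
  sign: inhibition
- class: prot_gene
  from: NICD
  to: NOTCH1
  sign: activation
- class: prot_prot
  from: gamma_secretase
  to: NICD
  sign: activation
- class: sig_prot
  from: Ca2+
  to: CAM
  sign: activation
- class: sig_prot
  from: Ca2+
  to: PSEN1
  sign: inhibition
- class: prot_prot
  from: PSEN1
  to: NICD
  sign: activation
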