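organism_id	gene_id	ko_term
G1	G1_g1	K1
G1	G1_g2	K1
G1	G1_g3	K2
G2	G2_g1	K2
G2	G2_g1	K3
G4	G4_g1	K4
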