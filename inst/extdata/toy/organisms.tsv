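organism_id	lineage_string	n_genes_total	n_16S_copies
G1	kingdom:Bacteria; phylum:Firmicutes; class:Bacilli; order:Bacillales; family:Planococcaceae; genus:Sporosarcina	4	4
G2	kingdom:Bacteria; phylum:Firmicutes; class:Bacilli; order:Bacillales; family:Planococcaceae; genus:Solibacillus	2	6
G4	kingdom:Bacteria; phylum:Proteobacteria; class:Gammaproteobacteria; order:Enterobacterales; family:Enterobacteriaceae; genus:Escherichia	5	7
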