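taxon_name	rank	parent_name	parent_rank
Bacteria	kingdom	NA	NA
Firmicutes	phylum	Bacteria	kingdom
Bacilli	class	Firmicutes	phylum
Bacillales	order	Bacilli	class
Planococcaceae	family	Bacillales	order
Sporosarcina	genus	Planococcaceae	family
Solibacillus	genus	Planococcaceae	family
Kurthia	genus	Planococcaceae	family
Proteobacteria	phylum	Bacteria	kingdom
Gammaproteobacteria	class	Proteobacteria	phylum
Enterobacterales	order	Gammaproteobacteria	class
Enterobacteriaceae	family	Enterobacterales	order
Escherichia	genus	Enterobacteriaceae	family
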