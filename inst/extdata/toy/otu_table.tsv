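#OTU ID	S1	taxonomy
OTU_1	10	k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Planococcaceae; g__Kurthia
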