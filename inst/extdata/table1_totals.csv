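clade,genera_sampled,genera_total,species_sampled,species_total
Lophiiformes,33,68,39,321
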