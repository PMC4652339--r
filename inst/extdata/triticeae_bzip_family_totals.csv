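species,total_genes
wheat,182
T_urartu,98
Ae_tauschii,96
barley,107
Brachypodium,88
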