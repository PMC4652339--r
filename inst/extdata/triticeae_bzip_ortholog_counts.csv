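species_a,species_b,n_orthologous,n_groups
wheat,T_urartu,76,49
wheat,Ae_tauschii,78,54
wheat,barley,110,64
wheat,Brachypodium,113,54
T_urartu,wheat,52,49
T_urartu,Ae_tauschii,68,65
T_urartu,barley,63,60
T_urartu,Brachypodium,50,45
Ae_tauschii,wheat,54,54
Ae_tauschii,T_urartu,66,65
Ae_tauschii,barley,61,61
Ae_tauschii,Brachypodium,51,49
barley,wheat,70,64
barley,T_urartu,65,60
barley,Ae_tauschii,69,61
barley,Brachypodium,78,72
Brachypodium,wheat,55,54
Brachypodium,T_urartu,53,45
Brachypodium,Ae_tauschii,54,49
Brachypodium,barley,72,72
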