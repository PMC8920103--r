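group,contribution,type
sulfate_Na,38.7,hydrophilic
carboxylate_K,21.1,hydrophilic
carboxylate_Na,19.1,hydrophilic
sulfonate_Na,11.0,hydrophilic
tertiary_amine,9.4,hydrophilic
ester_sorbitan_ring,6.8,hydrophilic
ester_free,2.4,hydrophilic
carboxylic_acid,2.1,hydrophilic
hydroxyl_free,1.9,hydrophilic
ether,1.3,hydrophilic
hydroxyl_sorbitan_ring,0.5,hydrophilic
CH_CH2_CH3_CH,-0.475,lipophilic
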