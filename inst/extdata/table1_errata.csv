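name,field,value,provenance
isoflurane,explogp,2.06,"back-solved from the published MG and DD2 delta values (both phases imply 2.060 +/- 0.001); equals the PubChem experimental log P for isoflurane, omitted from the published property table"
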