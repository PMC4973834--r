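study_id,level_a,level_b,rho,provenance
6,chalkley,all_vessels,0.55,patient_level_approx
13,chalkley,all_vessels,0.74,patient_level_approx
17,chalkley,all_vessels,0.27,patient_level_approx
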