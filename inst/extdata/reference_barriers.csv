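process,step_label,compound_id,barrier,reported_reduction_pct
biodegradation,phosphate_bond_cleavage_1,TCPP,249.4895,
biodegradation,phosphate_bond_cleavage_1,TCPP-OH,210.2360,15.73
photodegradation,o_oh_cleavage,TCPP,402.0239,
photodegradation,o_oh_cleavage,TCPP-OH,190.8840,52.52
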