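compound_id,binding_free_energy,reported_improvement_pct
TCPP,62.326,
TCPP-OH,−109.395,75.52
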