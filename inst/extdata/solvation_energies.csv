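compound_id,condition,transition_energy
TCPP,vacuum,7.29
TCPP,solvated,5.14
TCPP-OH,vacuum,5.47
TCPP-OH,solvated,4.07
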