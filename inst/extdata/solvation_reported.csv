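reference_compound,reference_condition,compound,condition,reported_reduction_pct
TCPP,solvated,TCPP-OH,solvated,20.88
TCPP,vacuum,TCPP,solvated,29.52
TCPP-OH,vacuum,TCPP-OH,solvated,25.74
TCPP,vacuum,TCPP-OH,solvated,44.23
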