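factor,level1,level2,level3,ranking
ph,−82.31,−75.11,−73.46,3
temperature,−76.75,−81.28,−72.85,4
methanol,−74.49,−75.19,−81.19,5
acetic_acid,−78.06,−75.48,−77.34,7
h2o2,−84.66,−71.56,−74.66,1
voltage,−71.28,−81.27,−78.32,2
surfactant,−77.44,−74.85,−78.59,6
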