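compound_id,r_biodegradation,r_photodegradation,score
TCEP,1.168,0.992,1.08
TCIPP,1.000,1.000,1.00
TCPP,3.454,0.991,2.22
TDCIPP,1.000,0.988,0.99
TDCPP,1.408,0.995,1.20
TPHP,1.321,0.757,1.04
EHDPP,1.357,0.748,1.05
TEP,1.517,0.746,1.13
TBOEP,1.718,0.939,1.33
TEHP,1.859,0.880,1.37
TPrP,6.539,0.873,3.71
BdPhP,1.251,0.748,1.00
TMP,7.292,0.883,4.09
TiBP,1.027,0.884,0.96
TPeP,1.947,0.869,1.41
TnPP,15.726,0.883,8.30
TmTP,1.515,0.730,1.12
TpTP,1.795,0.726,1.26
TBPP,1.628,0.600,1.11
TiPP,1.280,0.886,1.08
CDPP,1.443,0.745,1.09
IDPP,1.769,0.747,1.26
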