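compound_id,binding_free_energy,transition_energy,set_tag
TCEP,−123.731,7.2805,training
TCIPP,−144.537,7.2211,training
TCPP,−41.842,7.2874,training
TDCIPP,−144.5,7.1323,test
TDCPP,−203.57,7.1821,training
TPHP,−190.952,5.4695,training
EHDPP,−196.153,5.4015,training
TEP,−219.226,5.3858,training
TBOEP,−84.125,7.6896,test
TEHP,−268.708,8.2033,training
TPrP,−22.103,8.2739,training
BdPhP,−180.854,5.4003,training
TMP,−19.82,8.1823,training
TiBP,−148.43,8.1651,training
TPeP,−74.236,8.3083,training
TnPP,−9.191,8.1795,training
TmTP,−219.036,5.2731,test
TpTP,−259.422,5.2399,test
TBPP,−88.759,4.3292,training
TiPP,−112.943,8.1537,test
CDPP,−208.576,5.3779,training
IDPP,−255.722,5.3928,training
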